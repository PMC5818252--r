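#' Sweep configuration presets
#'
#' Bundles every stage's parameters for [run_sweep()].  `preset = "reduced"`
#' is the desk-scale default: an 11 x 11 lattice over the unit square, two
#' sessions per cell and 246 s of simulated time per session (6 s transient),
#' sized so a full sweep completes on one CPU in minutes.  `preset = "full"`
#' keeps the lattice but simulates 8 minutes after a 10 s transient with
#' five sessions per cell, matching the scale of the original in-silico
#' experiment.
#'
#' @param preset `"reduced"` or `"full"`.
#' @param sigma,gamma swept parameter values.
#' @param ... overrides for any listed field, e.g. `n_sessions`, `duration`
#'   (s), `transient` (s, discarded neural settling), `hemo_burn` (s of BOLD
#'   discarded while the hemodynamic states equilibrate, default 20),
#'   `density` (edge density for consistency thresholding), `consensus_runs`,
#'   `mtd_window` (samples), `bt_stride`, `bt_restarts`.
#' @return a list of class `sweep_config`.
#' @export
sweep_config <- function(preset = c("reduced", "full"),
                         sigma = seq(0, 1, 0.1), gamma = seq(0, 1, 0.1),
                         ...) {
  preset <- match.arg(preset)
  base <- list(
    sigma = sigma, gamma = gamma,
    n_sessions = if (preset == "reduced") 2L else 5L,
    duration = if (preset == "reduced") 246 else 490,
    transient = if (preset == "reduced") 6 else 10,
    phase_window = if (preset == "reduced") 60 else Inf,
    dt = 0.001, sample_dt = 0.005,
    noise_std = 1, m = 1.5, timescale = 20, conduction_speed = 3,
    hemo = hemodynamic_params(),
    hemo_burn = 20,
    band = c(0.01, 0.1),
    density = 0.10, resolution = 1, consensus_runs = 100,
    mtd_window = 15,
    bt_stride = if (preset == "reduced") 3L else 1L,
    bt_restarts = 10L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(base))
  if (length(bad)) stop("unknown sweep_config fields: ",
                        paste(bad, collapse = ", "))
  base[names(ov)] <- ov
  structure(base, class = "sweep_config")
}

.cell_seed <- function(master_seed, cell, session) {
  as.integer((master_seed + 104729 * cell + session) %% .Machine$integer.max)
}

#' Run the gain-by-excitability sweep
#'
#' For every (sigma, gamma) cell: simulate `n_sessions` sessions of the
#' delayed stochastic network, extract phase synchrony (order parameter mean
#' and SD), realized gain per region, BOLD functional connectivity per
#' session, time-resolved topology (MTD + windowed participation, session
#' 1), then consistency-threshold the session FC stack and summarize the
#' time-averaged topology.  Finally the critical boundary is located on the
#' synchrony grid.  Cells are cached to `cache_dir` (when given) keyed by
#' their exact configuration, so interrupted sweeps resume to an identical
#' result.
#'
#' @param c a [connectome()].
#' @param config a [sweep_config()].
#' @param master_seed integer; every cell/session seed derives from it.
#' @param cache_dir optional directory for cell-level caching/resume.
#' @param verbose print progress to stderr.
#' @return object of class `sweep_result`; see [summary.sweep_result()].
#' @export
run_sweep <- function(c, config = sweep_config("reduced"), master_seed = 1,
                      cache_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(c, "connectome"), inherits(config, "sweep_config"))
  sig <- config$sigma; gam <- config$gamma
  ns <- length(sig); ng <- length(gam)
  n <- c$n_regions
  if (!is.null(cache_dir))
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)

  grids <- c("rho_mean", "rho_sd", "Q", "Q_inv", "mean_BA",
             "global_efficiency", "mean_clustering",
             "mean_log10_communicability", "n_modules", "bt_var")
  res <- setNames(replicate(length(grids),
                            matrix(NA_real_, ns, ng), simplify = FALSE),
                  grids)
  BA <- array(NA_real_, c(ns, ng, n))
  RG <- array(NA_real_, c(ns, ng, n))
  fc_stacks <- vector("list", ns * ng)
  dim(fc_stacks) <- c(ns, ng)
  failures <- list()

  for (j in seq_len(ng)) for (i in seq_len(ns)) {
    cell <- (j - 1L) * ns + i
    key <- sprintf("cell_%03d.rds", cell)
    cell_cfg <- list(sigma = sig[i], gamma = gam[j], config = unclass(config),
                     master_seed = master_seed, cell = cell)
    rec <- NULL
    if (!is.null(cache_dir) && file.exists(file.path(cache_dir, key))) {
      cached <- readRDS(file.path(cache_dir, key))
      if (identical(cached$cfg, cell_cfg)) rec <- cached$rec
    }
    if (is.null(rec)) {
      rec <- tryCatch(
        .run_cell(c, sig[i], gam[j], config, master_seed, cell),
        error = function(e) e)
      if (inherits(rec, "error")) {
        failures[[length(failures) + 1]] <-
          list(sigma = sig[i], gamma = gam[j], message = conditionMessage(rec))
        next
      }
      if (!is.null(cache_dir))
        saveRDS(list(cfg = cell_cfg, rec = rec), file.path(cache_dir, key))
    }
    for (g in grids) res[[g]][i, j] <- rec[[g]]
    BA[i, j, ] <- rec$BA_region
    RG[i, j, ] <- rec$realized_gain
    fc_stacks[[i, j]] <- rec$fc_stack
    if (verbose)
      message(sprintf("cell %d/%d  sigma=%.2f gamma=%.2f  rho=%.3f",
                      cell, ns * ng, sig[i], gam[j], rec$rho_mean))
  }
  if (length(failures))
    warning(length(failures), " cell(s) failed; see $failures")

  regime <- matrix(ifelse(res$rho_mean >= 0.5, "synchronized",
                          "unsynchronized"), ns, ng)
  boundary <- detect_boundary(res$rho_mean, sig, gam)
  structure(c(list(sigma = sig, gamma = gam), res,
              list(regime = regime, BA_region = BA, realized_gain = RG,
                   fc_stacks = fc_stacks, boundary = boundary,
                   failures = failures,
                   provenance = list(master_seed = master_seed,
                                     config = unclass(config),
                                     n_regions = n,
                                     timestamp = format(Sys.time(), "%Y-%m-%d")))),
            class = "sweep_result")
}

## one lattice cell: simulate sessions, analyze synchrony, FC, temporal
## topology; returns a flat record
.run_cell <- function(c, sigma, gamma, config, master_seed, cell) {
  n <- c$n_regions
  S <- config$n_sessions
  fc_stack <- array(NA_real_, c(n, n, S))
  rho_means <- rho_sds <- numeric(S)
  rg_acc <- matrix(0, n, S)
  bt_var <- NA_real_
  for (s in seq_len(S)) {
    cfg <- sim_config(sigma = sigma, gamma = gamma, m = config$m,
                      timescale = config$timescale,
                      noise_std = config$noise_std, dt = config$dt,
                      duration = config$duration, transient = config$transient,
                      sample_dt = config$sample_dt,
                      conduction_speed = config$conduction_speed,
                      seed = .cell_seed(master_seed, cell, s),
                      n_sessions = 1)
    ts <- simulate_network(cfg, c)
    ## synchrony statistics converge within ~1 min of fast dynamics; a
    ## shorter phase window keeps the Hilbert stage cheap on long runs
    nph <- min(nrow(ts$V), round(config$phase_window / config$sample_dt))
    op <- order_parameter(instantaneous_phase(ts$V[seq_len(nph), ,
                                                   drop = FALSE]))
    rho_means[s] <- op$summary$rho_mean
    rho_sds[s] <- op$summary$rho_sd
    rg_acc[, s] <- realized_gain(ts$V, sigma, config$m)
    bold <- balloon_windkessel(ts, config$hemo)
    ## drop the hemodynamic settling window: the Balloon-Windkessel states
    ## need ~15-20 s to equilibrate and the shared settling ramp would
    ## otherwise masquerade as global functional connectivity
    burn <- min(ceiling(config$hemo_burn / bold$TR),
                nrow(bold$signal) - config$mtd_window - 3)
    if (burn > 0)
      bold <- bold_series(bold$signal[-seq_len(burn), , drop = FALSE],
                          bold$TR)
    bp <- bandpass(bold, config$band[1], config$band[2])
    fc_stack[, , s] <- functional_connectivity(bp)$z
    if (s == 1) {
      trfc <- mtd(bp, config$mtd_window)
      BT <- time_resolved_participation(trfc, n_restarts = config$bt_restarts,
                                        stride = config$bt_stride)
      bt_var <- topological_variability(BT)
    }
  }
  W_thr <- consistency_threshold(fc_stack, config$density)
  topo <- summarize_topology(W_thr, n_runs = config$consensus_runs,
                             resolution = config$resolution,
                             seed = .cell_seed(master_seed, cell, 0L))
  list(rho_mean = mean(rho_means), rho_sd = mean(rho_sds),
       Q = topo$Q, Q_inv = topo$Q_inv, mean_BA = topo$mean_BA,
       global_efficiency = topo$global_efficiency,
       mean_clustering = topo$mean_clustering,
       mean_log10_communicability = topo$mean_log10_communicability,
       n_modules = topo$n_modules, bt_var = bt_var,
       BA_region = topo$BA, realized_gain = rowMeans(rg_acc),
       fc_stack = fc_stack)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Gain-by-excitability sweep:", length(x$sigma), "x", length(x$gamma),
      "cells,", x$provenance$n_regions, "regions\n")
  cat("  synchronized cells:", sum(x$regime == "synchronized"),
      "/", length(x$regime), "\n")
  print(x$boundary)
  invisible(x)
}

#' Summarize a sweep
#'
#' Regime statistics across lattice cells: pooled-variance t-tests of each
#' topology metric between synchronized and unsynchronized cells.
#'
#' @param object a `sweep_result`.
#' @param ... unused.
#' @return data.frame (one row per metric) with group means, t, df, p.
#' @export
summary.sweep_result <- function(object, ...) {
  mets <- c("mean_BA", "Q", "global_efficiency", "mean_clustering",
            "mean_log10_communicability", "bt_var")
  rows <- lapply(mets, function(m) {
    tt <- tryCatch(regime_ttest(object[[m]], object$regime),
                   error = function(e)
                     list(t = NA_real_, df = NA_real_, p = NA_real_,
                          mean_sync = NA_real_, mean_unsync = NA_real_))
    data.frame(metric = m, mean_sync = tt$mean_sync,
               mean_unsync = tt$mean_unsync, t = tt$t, df = tt$df, p = tt$p)
  })
  do.call(rbind, rows)
}

#' Heatmaps of sweep grids with the critical boundary overlaid
#'
#' @param x a `sweep_result`.
#' @param metrics which grids to draw.
#' @param ... passed to [graphics::image()].
#' @export
plot.sweep_result <- function(x, metrics = c("rho_mean", "mean_BA", "Q",
                                             "mean_log10_communicability"),
                              ...) {
  op <- par(mfrow = c(ceiling(length(metrics) / 2), 2),
            mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (m in metrics) {
    image(x$sigma, x$gamma, x[[m]], col = hcl.colors(64, "viridis"),
          xlab = expression(sigma), ylab = expression(gamma), main = m, ...)
    ok <- x$boundary$sigma_valid
    if (any(ok))
      lines(x$boundary$sigma_crit[ok], x$gamma[ok], lwd = 2, col = "white",
            lty = 2)
  }
  invisible(x)
}

#' Pooled-variance two-sample t-test between synchrony regimes
#'
#' Student t-test (equal-variance pooling, df = n1 + n2 - 2) of a metric
#' between synchronized and unsynchronized lattice cells.  The sign is
#' synchronized minus unsynchronized.
#'
#' @param metric_grid numeric matrix/vector of the metric per cell.
#' @param regimes character matrix/vector (`"synchronized"` /
#'   `"unsynchronized"`) or logical (TRUE = synchronized).
#' @return list with `t`, `df`, `p`, `mean_sync`, `mean_unsync`.
#' @export
regime_ttest <- function(metric_grid, regimes) {
  x <- as.vector(metric_grid)
  r <- if (is.logical(regimes)) regimes else as.vector(regimes) == "synchronized"
  ok <- is.finite(x) & !is.na(r)
  a <- x[ok & r]; b <- x[ok & !r]
  if (length(a) < 2 || length(b) < 2)
    stop("each regime needs at least 2 cells")
  tt <- .pooled_t(a, b)
  c(tt, list(mean_sync = mean(a), mean_unsync = mean(b)))
}

## Student t with pooled variance; t defined as 0 for degenerate
## zero-variance comparisons
.pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) 0 else (mean(a) - mean(b)) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Lattice cells in the boundary-aligned comparison band
#'
#' Regime statistics follow the boundary-aligned construction: only
#' excitability rows that actually cross the critical boundary inside the
#' alignment band contribute, so that both regimes are present in every row
#' compared.  (Rows without a crossing — e.g. gain-insensitive rows, or the
#' metastable low-excitability strip where integration rises while the
#' time-mean order parameter stays below threshold — cannot be aligned.)
#'
#' @param sweep a `sweep_result`.
#' @param range gamma band, default `c(0.2, 0.6)` (the sigma-alignment
#'   averaging range).
#' @return logical matrix over lattice cells.
#' @export
boundary_band_cells <- function(sweep, range = c(0.2, 0.6)) {
  eps <- 1e-9
  cols <- sweep$gamma >= range[1] - eps & sweep$gamma <= range[2] + eps &
    sweep$boundary$sigma_valid
  matrix(rep(cols, each = length(sweep$sigma)),
         length(sweep$sigma), length(sweep$gamma))
}

#' Per-edge functional-connectivity change between regimes
#'
#' Mean session-averaged FC of every edge across synchronized cells minus
#' its mean across unsynchronized cells.
#'
#' @param sweep a `sweep_result`.
#' @param cells optional logical matrix (e.g. [boundary_band_cells()])
#'   restricting which lattice cells enter the comparison.
#' @return symmetric n x n matrix of FC (Fisher z) changes.
#' @export
fc_regime_change <- function(sweep, cells = NULL) {
  sync <- sweep$regime == "synchronized"
  use <- if (is.null(cells)) rep(TRUE, length(sync)) else as.vector(cells)
  cellmean <- function(idx) {
    mats <- lapply(which(idx & use), function(k) {
      st <- sweep$fc_stacks[[k]]
      if (is.null(st)) return(NULL)
      apply(st, c(1, 2), mean)
    })
    mats <- Filter(Negate(is.null), mats)
    if (!length(mats)) stop("a regime has no completed cells")
    Reduce(`+`, mats) / length(mats)
  }
  cellmean(sync) - cellmean(!sync)
}

#' Hemisphere contrast of functional-connectivity changes
#'
#' Groups per-edge FC changes by within- versus between-hemisphere pair
#' masks and compares the groups with a pooled-variance t-test over edges
#' (df = number of pairs - 2).  Positive t means the between-hemisphere
#' change is larger.
#'
#' @param dz symmetric matrix of per-edge changes (e.g.
#'   [fc_regime_change()]).
#' @param masks a [hemisphere_edge_masks()] result.
#' @return list with group means and SDs, `t`, `df`, `p`.
#' @export
hemisphere_contrast <- function(dz, masks) {
  ut <- upper.tri(dz)
  wi <- dz[ut & masks$within]
  be <- dz[ut & masks$between]
  if (!length(wi) || !length(be)) stop("empty hemisphere mask")
  tt <- .pooled_t(be, wi)
  c(list(within_mean = mean(wi), within_sd = stats::sd(wi),
         between_mean = mean(be), between_sd = stats::sd(be)), tt)
}

#' Reliability of topology grids across edge densities
#'
#' Re-thresholds every cell's stored FC stack at each candidate density,
#' recomputes the topology metrics, and correlates each metric's lattice
#' against the reference-density lattice — the robustness check that the
#' topological landscape does not hinge on one threshold.  Optionally
#' restricts the comparison to cells whose consensus partition has a fixed
#' module count.
#'
#' @param sweep a `sweep_result`.
#' @param densities candidate densities (default 0.05-0.20).
#' @param reference reference density (default 0.10).
#' @param n_runs Louvain runs per consensus during the scan (default 20,
#'   lighter than the main sweep).
#' @param module_match optional module count N: correlate only cells with
#'   `n_modules == N` at the reference density.
#' @param seed RNG seed for the scan.
#' @return data.frame with columns density, metric, r.
#' @export
reliability_scan <- function(sweep, densities = seq(0.05, 0.20, 0.05),
                             reference = 0.10, n_runs = 20,
                             module_match = NULL, seed = 1) {
  if (length(densities) < 2 && !(reference %in% densities))
    stop("need at least 2 densities")
  mets <- c("Q", "mean_BA", "global_efficiency",
            "mean_log10_communicability")
  cells <- which(!vapply(sweep$fc_stacks, is.null, logical(1)))
  grid_at <- function(d) {
    set.seed(seed)
    out <- matrix(NA_real_, length(sweep$fc_stacks), length(mets) + 1)
    for (k in cells) {
      W <- consistency_threshold(sweep$fc_stacks[[k]], d)
      topo <- summarize_topology(W, n_runs = n_runs)
      out[k, ] <- c(topo$Q, topo$mean_BA, topo$global_efficiency,
                    topo$mean_log10_communicability, topo$n_modules)
    }
    colnames(out) <- c(mets, "n_modules")
    out
  }
  ref <- grid_at(reference)
  keep <- rep(TRUE, nrow(ref))
  if (!is.null(module_match)) keep <- ref[, "n_modules"] %in% module_match
  rows <- list()
  for (d in densities) {
    g <- if (identical(d, reference)) ref else grid_at(d)
    for (m in mets) {
      ok <- keep & is.finite(ref[, m]) & is.finite(g[, m])
      rows[[length(rows) + 1]] <-
        data.frame(density = d, metric = m,
                   r = stats::cor(ref[ok, m], g[ok, m]))
    }
  }
  do.call(rbind, rows)
}

#' Write sweep tables and figures
#'
#' Exports every lattice grid as TSV (deterministic, 17-digit precision),
#' the critical boundary, boundary-aligned curves for the synchrony SD,
#' communicability and topological variability, the regime t-test summary,
#' and PNG heatmaps.
#'
#' @param sweep a `sweep_result`.
#' @param out_dir output directory (created on demand).
#' @param figures also write PNG heatmaps (default TRUE).
#' @return invisibly, the file manifest.
#' @export
report_sweep <- function(sweep, out_dir, figures = TRUE) {
  if (length(sweep$failures))
    stop("sweep incomplete: ", length(sweep$failures), " failed cell(s)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  grids <- c("rho_mean", "rho_sd", "Q", "Q_inv", "mean_BA",
             "global_efficiency", "mean_clustering",
             "mean_log10_communicability", "n_modules", "bt_var")
  for (g in grids) {
    p <- file.path(out_dir, paste0(g, ".tsv"))
    .write_matrix_tsv(sweep[[g]], p, col_names = .fmt_num(sweep$gamma))
    manifest <- c(manifest, p)
  }
  bt <- data.frame(gamma = sweep$gamma,
                   sigma_crit = sweep$boundary$sigma_crit)
  p <- file.path(out_dir, "boundary.tsv")
  utils::write.table(data.frame(lapply(bt, .fmt_num)), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- c(manifest, p)
  for (g in c("rho_sd", "mean_log10_communicability", "bt_var", "mean_BA")) {
    al <- tryCatch(align_to_boundary(sweep[[g]], sweep$boundary, "sigma"),
                   error = function(e) NULL)   # no crossings: nothing to align
    if (is.null(al)) next
    p <- file.path(out_dir, paste0("aligned_", g, ".tsv"))
    utils::write.table(data.frame(lapply(al, .fmt_num)), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- c(manifest, p)
  }
  p <- file.path(out_dir, "regime_ttests.tsv")
  s <- summary.sweep_result(sweep)
  s[-1] <- lapply(s[-1], .fmt_num)
  utils::write.table(s, p, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(manifest, p)
  if (figures) {
    p <- file.path(out_dir, "sweep_heatmaps.png")
    grDevices::png(p, width = 1200, height = 900, res = 120)
    plot(sweep)
    grDevices::dev.off()
    manifest <- c(manifest, p)
  }
  invisible(manifest)
}
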