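## Hilbert analytic signal via FFT: standard one-sided spectrum doubling
.analytic_signal <- function(x) {
  T <- length(x)
  u <- numeric(T)
  if (T %% 2 == 0) {
    u[1] <- 1; u[T / 2 + 1] <- 1
    u[2:(T / 2)] <- 2
  } else {
    u[1] <- 1
    u[2:((T + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * u, inverse = TRUE) / T
}

#' Instantaneous oscillation phase
#'
#' Per region: remove the least-squares linear trend, take the phase of the
#' analytic signal (Hilbert transform), and drop a fraction of samples at
#' each end to suppress transform edge effects.
#'
#' @param x a [neural_ts()] (phase of `V`) or a time x region matrix.
#' @param trim fraction of samples dropped at each end (default 0.05).
#' @return time x region matrix of phases in `(-pi, pi]`.
#' @export
instantaneous_phase <- function(x, trim = 0.05) {
  m <- if (inherits(x, "neural_ts")) x$V else as.matrix(x)
  T <- nrow(m)
  if (T < 8) stop("need more samples to estimate phase")
  if (any(apply(m, 2, stats::sd) == 0))
    stop("constant channel: phase undefined")
  tt <- seq_len(T)
  X <- cbind(1, tt)
  m <- m - X %*% qr.solve(X, m)          # least-squares detrend, all columns
  th <- apply(m, 2, function(col) Arg(.analytic_signal(col)))
  keep <- seq.int(floor(T * trim) + 1, T - floor(T * trim))
  th[keep, , drop = FALSE]
}

#' Phase summary of a simulated session
#'
#' @param rho_mean time-mean of the order parameter.
#' @param rho_sd its standard deviation over time.
#' @return object of class `phase_summary` with the regime label
#'   (synchronized iff `rho_mean >= 0.5`).
#' @export
phase_summary <- function(rho_mean, rho_sd) {
  structure(list(rho_mean = rho_mean, rho_sd = rho_sd,
                 regime = classify_regime(rho_mean)),
            class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat("Order parameter: mean", signif(x$rho_mean, 4), "sd",
      signif(x$rho_sd, 4), "->", x$regime, "\n")
  invisible(x)
}

#' Kuramoto phase-synchrony order parameter
#'
#' \deqn{\rho(t) = | N^{-1} \sum_j e^{i \theta_j(t)} |,} the magnitude of the
#' mean unit phase vector across regions: 1 when all regions share a phase,
#' near 0 for uniformly scattered phases.
#'
#' @param theta time x region phase matrix (radians).
#' @return list with `rho` (the time course) and `summary`
#'   (a [phase_summary()]).
#' @export
order_parameter <- function(theta) {
  theta <- as.matrix(theta)
  if (ncol(theta) < 2) stop("need at least 2 regions")
  rho <- Mod(rowMeans(exp(1i * theta)))
  list(rho = rho, summary = phase_summary(mean(rho), stats::sd(rho)))
}

#' Classify a synchrony regime
#'
#' Synchronized iff the time-mean order parameter is at least 0.5 (the
#' threshold is inclusive on the synchronized side).
#'
#' @param rho_mean value in `[0, 1]`.
#' @return `"synchronized"` or `"unsynchronized"`.
#' @export
classify_regime <- function(rho_mean) {
  if (!is.finite(rho_mean) || rho_mean < 0 || rho_mean > 1)
    stop("rho_mean must lie in [0, 1]")
  if (rho_mean >= 0.5) "synchronized" else "unsynchronized"
}

#' Locate the critical boundary on a gain-by-excitability lattice
#'
#' For every excitability row the first gain value at which the regime flips
#' (linearly interpolating the `rho = 0.5` crossing), and symmetrically for
#' every gain column; rows/columns without a crossing are flagged invalid.
#'
#' @param rho_grid matrix of time-mean order parameters with `sigma` along
#'   rows and `gamma` along columns.
#' @param sigma,gamma the swept parameter values.
#' @return object of class `critical_boundary` with `sigma_crit` (per
#'   gamma), `gamma_crit` (per sigma) and validity flags.
#' @export
detect_boundary <- function(rho_grid, sigma, gamma) {
  rho_grid <- as.matrix(rho_grid)
  stopifnot(nrow(rho_grid) == length(sigma), ncol(rho_grid) == length(gamma),
            all(is.finite(rho_grid)))
  cross1d <- function(vals, pars) {
    s <- vals >= 0.5
    flip <- which(s[-1] != s[-length(s)])
    if (!length(flip)) return(NA_real_)
    i <- flip[1]                         # first flip; ties toward smaller par
    p <- pars[i] + (0.5 - vals[i]) * (pars[i + 1] - pars[i]) /
      (vals[i + 1] - vals[i])
    p
  }
  sc <- apply(rho_grid, 2, cross1d, pars = sigma)
  gc <- apply(rho_grid, 1, cross1d, pars = gamma)
  structure(list(sigma = sigma, gamma = gamma,
                 sigma_crit = sc, sigma_valid = !is.na(sc),
                 gamma_crit = gc, gamma_valid = !is.na(gc)),
            class = "critical_boundary")
}

#' @export
print.critical_boundary <- function(x, ...) {
  cat("Critical boundary:", sum(x$sigma_valid), "/", length(x$gamma),
      "gamma rows cross in sigma;", sum(x$gamma_valid), "/", length(x$sigma),
      "sigma rows cross in gamma\n")
  invisible(x)
}

#' Boundary-aligned average of a metric grid
#'
#' Shifts each row (or column) of a metric grid so that its critical crossing
#' sits at offset zero, interpolates onto a common offset grid with the same
#' spacing as the sweep, and averages across the rows inside `range` — the
#' construction behind boundary-aligned profiles such as "mean across
#' 0.2 <= gamma <= 0.6".
#'
#' @param metric_grid matrix shaped like the sweep (`sigma` rows x `gamma`
#'   columns).
#' @param boundary a [detect_boundary()] result.
#' @param axis `"sigma"`: align each gamma column along sigma (averaging over
#'   gamma in `range`); `"gamma"`: the transpose operation.
#' @param range length-2 numeric: which values of the *other* parameter to
#'   average over (defaults: gamma in `[0.2, 0.6]` for sigma alignment,
#'   sigma in `[0.3, 1.0]` for gamma alignment).
#' @return data.frame with `offset`, `value` (mean across aligned rows) and
#'   `n` (rows contributing at that offset).
#' @export
align_to_boundary <- function(metric_grid, boundary, axis = c("sigma", "gamma"),
                              range = NULL) {
  axis <- match.arg(axis)
  metric_grid <- as.matrix(metric_grid)
  if (axis == "sigma") {
    pars <- boundary$sigma; other <- boundary$gamma
    crit <- boundary$sigma_crit
    range <- range %||% c(0.2, 0.6)
    cols <- lapply(seq_along(other), function(j) metric_grid[, j])
  } else {
    pars <- boundary$gamma; other <- boundary$sigma
    crit <- boundary$gamma_crit
    range <- range %||% c(0.3, 1.0)
    cols <- lapply(seq_along(other), function(j) metric_grid[j, ])
  }
  use <- which(other >= range[1] & other <= range[2] & !is.na(crit))
  if (!length(use)) stop("empty averaging range: no valid crossings inside it")
  step <- stats::median(diff(pars))
  off <- seq(-(max(pars) - min(pars)), max(pars) - min(pars), by = step)
  acc <- sapply(use, function(j)
    stats::approx(pars - crit[j], cols[[j]], xout = off)$y)
  acc <- matrix(acc, nrow = length(off))
  data.frame(offset = off,
             value = rowMeans(acc, na.rm = TRUE),
             n = rowSums(!is.na(acc)))
}

#' Dwell times and Pareto (power-law) tail analysis
#'
#' Splits a series into excursions relative to a threshold, measures the
#' dwell time of each excursion, and fits the tail by maximum likelihood:
#' continuous Pareto exponent `alpha = 1 + n / sum(log(x/xmin))` with the
#' lower cutoff chosen by Kolmogorov-Smirnov minimization, compared against
#' an exponential tail by log-likelihood ratio.  Near criticality dwell
#' times are heavy tailed; deep inside a regime they die off exponentially.
#'
#' @param x numeric series (e.g. the order parameter over time, or one
#'   region's potential).
#' @param threshold excursion threshold (default 0.5, the regime threshold).
#' @param dt time per sample (durations are reported in these units).
#' @param min_excursions minimum number of complete excursions required
#'   (default 50).
#' @return list with `durations`, `alpha`, `xmin`, `loglik_ratio`
#'   (positive favors the power law) and `verdict`
#'   (`"power-law"` or `"exponential"`).
#' @export
dwell_time_tail <- function(x, threshold = 0.5, dt = 1, min_excursions = 50) {
  above <- x >= threshold
  r <- rle(above)
  len <- r$lengths
  if (length(len) > 2) len <- len[-c(1, length(len))]  # drop partial runs
  else len <- integer(0)
  durations <- len * dt
  if (length(durations) < min_excursions)
    stop("too few excursions (", length(durations), ") for tail fitting")
  c(list(durations = durations), pareto_tail_fit(durations))
}

#' Maximum-likelihood Pareto tail fit with exponential comparison
#'
#' Continuous power-law exponent `alpha = 1 + n / sum(log(x/xmin))` with the
#' lower cutoff `xmin` chosen by Kolmogorov-Smirnov minimization, compared on
#' the same tail against a shifted-exponential fit by log-likelihood ratio.
#'
#' @param x positive durations (or any positive samples).
#' @return list with `alpha`, `xmin`, `n_tail`, `loglik_ratio` (positive
#'   favors the power law) and `verdict`.
#' @export
pareto_tail_fit <- function(x) {
  fit <- .plfit(x)
  tail_x <- x[x >= fit$xmin]
  lambda <- 1 / max(mean(tail_x) - fit$xmin, .Machine$double.eps)
  ll_exp <- sum(log(lambda) - lambda * (tail_x - fit$xmin))
  ll_pl <- sum(log((fit$alpha - 1) / fit$xmin) -
                 fit$alpha * log(tail_x / fit$xmin))
  lr <- ll_pl - ll_exp
  list(alpha = fit$alpha, xmin = fit$xmin, n_tail = length(tail_x),
       loglik_ratio = lr,
       verdict = if (lr > 0) "power-law" else "exponential")
}

## continuous power-law MLE with KS-minimizing xmin (Clauset-style)
.plfit <- function(x, n_candidates = 50) {
  x <- x[x > 0]
  cands <- unique(stats::quantile(x, seq(0, 0.9, length.out = n_candidates),
                                  type = 1, names = FALSE))
  best <- NULL
  for (xm in cands) {
    tail_x <- x[x >= xm]
    if (length(tail_x) < 10) next
    alpha <- 1 + length(tail_x) / sum(log(tail_x / xm))
    if (!is.finite(alpha) || alpha <= 1) next
    xs <- sort(tail_x)
    cdf_fit <- 1 - (xs / xm)^(1 - alpha)
    ecdf_lo <- (seq_along(xs) - 1) / length(xs)
    ecdf_hi <- seq_along(xs) / length(xs)
    D <- max(pmax(abs(cdf_fit - ecdf_lo), abs(cdf_fit - ecdf_hi)))
    if (is.null(best) || D < best$D)
      best <- list(alpha = alpha, xmin = xm, D = D)
  }
  if (is.null(best)) stop("power-law fit failed: no usable tail")
  best
}
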