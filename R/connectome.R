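#' Directed weighted structural connectome
#'
#' Container for a directed, weighted anatomical connectivity matrix plus the
#' fiber tract lengths that determine inter-regional conduction delays.  The
#' orientation convention is fixed throughout the package: `weights[i, j]` is
#' the strength of the projection from source region `j` onto target region
#' `i` (so `weights %*% rates` gives each region's afferent drive).
#'
#' @param weights n x n non-negative matrix of directed connection strengths
#'   (row = target, column = source).  The diagonal must be zero; non-zero
#'   diagonals are zeroed with a warning.
#' @param tract_lengths n x n non-negative matrix of fiber lengths in mm.
#'   Must be positive wherever `weights` is positive.
#' @param region_labels character vector of region names (default R1..Rn).
#' @param hemisphere character vector with entries `"left"` or `"right"`.
#' @return An object of class `connectome`.
#' @examples
#' w <- matrix(c(0, 1, 2, 0), 2, 2); l <- matrix(c(0, 30, 40, 0), 2, 2)
#' connectome(w, l, hemisphere = c("left", "right"))
#' @export
connectome <- function(weights, tract_lengths,
                       region_labels = NULL, hemisphere = NULL) {
  weights <- as.matrix(weights)
  tract_lengths <- as.matrix(tract_lengths)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop("weights must be square")
  if (!all(dim(tract_lengths) == c(n, n)))
    stop("dimension mismatch: weights is ", n, "x", n, " but tract_lengths is ",
         nrow(tract_lengths), "x", ncol(tract_lengths))
  if (any(!is.finite(weights)) || any(!is.finite(tract_lengths)))
    stop("non-finite entries in connectome matrices")
  if (any(weights < 0))
    stop("negative weight found; connection strengths must be non-negative")
  if (any(tract_lengths < 0))
    stop("negative tract length found")
  if (any(diag(weights) != 0)) {
    warning("self-connections are not allowed; zeroing the diagonal of weights")
    diag(weights) <- 0
  }
  if (any(weights > 0 & tract_lengths <= 0))
    stop("tract length must be positive wherever a connection weight is positive")
  region_labels <- region_labels %||% paste0("R", seq_len(n))
  if (length(region_labels) != n)
    stop("region_labels must have one entry per region")
  if (is.null(hemisphere))
    stop("missing hemisphere labels")
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != n)
    stop("hemisphere must have exactly ", n, " entries")
  bad <- setdiff(unique(hemisphere), c("left", "right"))
  if (length(bad))
    stop("unknown hemisphere label: ", paste(bad, collapse = ", "))
  structure(list(n_regions = n, weights = weights,
                 tract_lengths = tract_lengths,
                 region_labels = as.character(region_labels),
                 hemisphere = hemisphere),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  nnz <- sum(x$weights > 0)
  cat("Directed weighted connectome\n")
  cat("  regions:    ", x$n_regions, " (",
      sum(x$hemisphere == "left"), " left / ",
      sum(x$hemisphere == "right"), " right)\n", sep = "")
  cat("  edges:      ", nnz, "  (density ",
      signif(nnz / (x$n_regions * (x$n_regions - 1)), 3), ")\n", sep = "")
  cat("  weight:      mean ", signif(mean(x$weights[x$weights > 0]), 4),
      ", max ", signif(max(x$weights), 4), "\n", sep = "")
  cat("  tract (mm):  median ",
      signif(stats::median(x$tract_lengths[x$weights > 0]), 4), "\n", sep = "")
  invisible(x)
}

#' Read a connectome from disk
#'
#' Two formats are supported.  `"csv-pair"` expects a directory (or a named
#' character vector with entries `weights`, `tract_lengths`, `regions`)
#' holding `weights.csv` and `tract_lengths.csv` as headerless numeric
#' matrices and `regions.csv` with columns `label,hemisphere`.  `"graphml"`
#' expects edge attributes `weight` and `length_mm` and a node attribute
#' `hemisphere`.
#'
#' @param path directory, file triplet (csv-pair) or file (graphml).
#' @param format `"csv-pair"` or `"graphml"`.
#' @return A validated [connectome()].
#' @export
load_connectome <- function(path, format = c("csv-pair", "graphml")) {
  format <- match.arg(format)
  if (format == "csv-pair") {
    if (length(path) == 1 && dir.exists(path)) {
      path <- c(weights = file.path(path, "weights.csv"),
                tract_lengths = file.path(path, "tract_lengths.csv"),
                regions = file.path(path, "regions.csv"))
    }
    if (!all(c("weights", "tract_lengths", "regions") %in% names(path)))
      stop("csv-pair path must be a directory or a named vector with ",
           "'weights', 'tract_lengths' and 'regions'")
    for (p in path) if (!file.exists(p)) stop("file not found: ", p)
    w <- as.matrix(utils::read.csv(path[["weights"]], header = FALSE))
    l <- as.matrix(utils::read.csv(path[["tract_lengths"]], header = FALSE))
    dimnames(w) <- dimnames(l) <- NULL
    if (!is.numeric(w) || !is.numeric(l))
      stop("connectome matrices must parse as numeric")
    meta <- utils::read.csv(path[["regions"]], stringsAsFactors = FALSE)
    if (!all(c("label", "hemisphere") %in% names(meta)))
      stop("regions.csv must have columns 'label' and 'hemisphere'")
    connectome(w, l, meta$label, meta$hemisphere)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    ea <- igraph::edge_attr_names(g)
    if (!all(c("weight", "length_mm") %in% ea))
      stop("graphml edges need 'weight' and 'length_mm' attributes")
    if (!("hemisphere" %in% igraph::vertex_attr_names(g)))
      stop("missing hemisphere labels in graphml node attributes")
    n <- igraph::vcount(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    w <- matrix(0, n, n); l <- matrix(0, n, n)
    ## graphml edge u -> v is a projection from u onto v: row = target
    w[cbind(el[, 2], el[, 1])] <- igraph::E(g)$weight
    l[cbind(el[, 2], el[, 1])] <- igraph::E(g)$length_mm
    labs <- igraph::vertex_attr(g, "name") %||% paste0("R", seq_len(n))
    connectome(w, l, labs, igraph::vertex_attr(g, "hemisphere"))
  }
}

#' Write a connectome as a csv-pair directory
#'
#' Numbers are written with 17 significant digits so that
#' [load_connectome()] round-trips bit-exactly.
#'
#' @param x a [connectome()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path) {
  stopifnot(inherits(x, "connectome"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) {
    utils::write.table(matrix(.fmt_num(m), nrow = nrow(m)),
                       file.path(path, f), sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  wm(x$weights, "weights.csv")
  wm(x$tract_lengths, "tract_lengths.csv")
  utils::write.csv(data.frame(label = x$region_labels,
                              hemisphere = x$hemisphere),
                   file.path(path, "regions.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Inter-regional conduction delays
#'
#' Delays are tract length divided by conduction speed, reported in ms
#' (lengths in mm, speed in mm/ms).  Entries without a structural connection
#' are set to zero by convention.
#'
#' @param c a [connectome()].
#' @param speed conduction speed in mm/ms (default 3, a common large-scale
#'   modeling value; the underlying experiment does not pin one down).
#' @return An object of class `delay_matrix` with fields `delays` (ms) and
#'   `conduction_speed`.
#' @export
compute_delays <- function(c, speed = 3) {
  stopifnot(inherits(c, "connectome"))
  if (!is.numeric(speed) || length(speed) != 1 || speed <= 0)
    stop("conduction speed must be a positive scalar (mm/ms)")
  d <- c$tract_lengths / speed
  d[c$weights == 0] <- 0
  structure(list(delays = d, conduction_speed = speed),
            class = "delay_matrix")
}

#' @export
print.delay_matrix <- function(x, ...) {
  nz <- x$delays[x$delays > 0]
  cat("Conduction delays (speed ", x$conduction_speed, " mm/ms): ",
      length(nz), " connections, median ", signif(stats::median(nz), 3),
      " ms, max ", signif(max(c(nz, 0)), 3), " ms\n", sep = "")
  invisible(x)
}

#' Within- and between-hemisphere edge masks
#'
#' Partitions all unordered region pairs into within-hemisphere and
#' between-hemisphere sets, used by the hemisphere contrast on functional
#' connectivity changes.  For a 38/38 split of 76 regions this yields 1406
#' within- and 1444 between-hemisphere pairs (2850 in total).
#'
#' @param c a [connectome()].
#' @return list with logical n x n matrices `within` and `between`
#'   (symmetric, FALSE diagonal) and the pair counts `n_within`,
#'   `n_between`.
#' @export
hemisphere_edge_masks <- function(c) {
  stopifnot(inherits(c, "connectome"))
  h <- c$hemisphere
  same <- outer(h, h, "==")
  diag(same) <- FALSE
  diff <- outer(h, h, "!=")   # FALSE on the diagonal by construction
  ut <- upper.tri(same)
  list(within = same, between = diff,
       n_within = sum(same[ut]), n_between = sum(diff[ut]))
}
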