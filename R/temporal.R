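#' Time-resolved coupling by Multiplication of Temporal Derivatives
#'
#' For each region pair the pointwise product of z-scored first differences,
#' smoothed by a simple moving average of length `w`: windows of coherent
#' signal change score high, so the resulting region x region x window array
#' is a time-resolved (signed, weighted) coupling estimate.  `w = 1` returns
#' the raw normalized derivative products.
#'
#' @param b a [bold_series()] or time x region matrix.
#' @param w moving-average window in samples (default 15).
#' @return object of class `trfc`: list with `M` (region x region x window
#'   array, symmetric in its first two indices) and `w`.
#' @export
mtd <- function(b, w = 15) {
  x <- if (inherits(b, "bold_series")) b$signal else as.matrix(b)
  T <- nrow(x); n <- ncol(x)
  if (w < 1) stop("window must be at least 1 sample")
  if (T <= w + 1) stop("series too short for window ", w)
  d <- diff(x)
  d <- scale(d)                      # z-score the derivatives per region
  d[!is.finite(d)] <- 0
  Td <- nrow(d)
  nw <- Td - w + 1
  ## products as a (T-1) x n^2 matrix, then moving mean via cumulative sums
  P <- d[, rep(seq_len(n), each = n)] * d[, rep(seq_len(n), times = n)]
  cs <- rbind(0, apply(P, 2, cumsum))
  Mflat <- (cs[(w + 1):(Td + 1), , drop = FALSE] -
              cs[1:nw, , drop = FALSE]) / w
  M <- array(t(Mflat), dim = c(n, n, nw))
  structure(list(M = M, w = w), class = "trfc")
}

#' @export
print.trfc <- function(x, ...) {
  cat("Time-resolved FC:", dim(x$M)[1], "regions x", dim(x$M)[3],
      "windows (w =", x$w, ")\n")
  invisible(x)
}

#' Time-resolved participation coefficient
#'
#' Applies signed Louvain community detection and the participation
#' coefficient to each windowed coupling matrix, yielding each region's
#' between-module participation over time (B_T).  Windows whose matrix is
#' all zero are flagged and scored 0.
#'
#' @param trfc a [mtd()] result.
#' @param n_restarts Louvain restarts per window (default 10).
#' @param stride evaluate every `stride`-th window (default 1: all windows).
#' @param partition optional fixed `partition` (or membership vector): when
#'   given, windowed matrices inherit this partition instead of being
#'   re-clustered.
#' @param seed optional RNG seed.
#' @return region x window matrix of participation coefficients with the
#'   window indices as attribute `windows`.
#' @export
time_resolved_participation <- function(trfc, n_restarts = 10, stride = 1,
                                        partition = NULL, seed = NULL) {
  stopifnot(inherits(trfc, "trfc"), stride >= 1)
  if (!is.null(seed)) set.seed(seed)
  nw <- dim(trfc$M)[3]
  n <- dim(trfc$M)[1]
  wins <- seq.int(1, nw, by = stride)
  memb_fixed <- if (!is.null(partition)) {
    if (inherits(partition, "partition")) partition$membership
    else as.integer(partition)
  }
  BT <- matrix(0, n, length(wins))
  for (k in seq_along(wins)) {
    Wt <- trfc$M[, , wins[k]]
    if (all(Wt == 0)) {
      warning("all-zero coupling window ", wins[k], "; B_T set to 0")
      next
    }
    memb <- memb_fixed %||%
      louvain_signed(Wt, n_restarts = n_restarts)$membership
    BT[, k] <- participation_coefficient(Wt, memb)
  }
  attr(BT, "windows") <- wins
  BT
}

#' Topological variability of time-resolved participation
#'
#' The per-region standard deviation of B_T over windows, averaged across
#' regions — the scalar used to quantify how much network topology
#' fluctuates over time at a given parameter point.
#'
#' @param BT region x window matrix from [time_resolved_participation()].
#' @return non-negative scalar.
#' @export
topological_variability <- function(BT) {
  BT <- as.matrix(BT)
  if (ncol(BT) < 2) stop("need at least 2 windows")
  mean(apply(BT, 1, stats::sd))
}
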