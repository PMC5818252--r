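## binarized directed adjacency and total (in + out) degree
.binary_digraph <- function(c) {
  A <- (c$weights > 0) * 1
  diag(A) <- 0
  list(A = A, degree = rowSums(A) + colSums(A))
}

#' Rich-club coefficient of a directed network
#'
#' Removes every node whose total (in + out) binary degree is at most `k`
#' and reports the density of the surviving subnetwork: the number of
#' directed edges present divided by the `N_k (N_k - 1)` possible ones.
#' Undefined (NA) when fewer than two nodes survive.
#'
#' @param c a [connectome()] (its binarized weights are used).
#' @param k degree threshold (>= 0).
#' @return scalar in `[0, 1]`, or NA when undefined.
#' @export
rich_club_coefficient <- function(c, k) {
  stopifnot(k >= 0)
  bg <- .binary_digraph(c)
  keep <- bg$degree > k
  Nk <- sum(keep)
  if (Nk < 2) return(NA_real_)
  sum(bg$A[keep, keep]) / (Nk * (Nk - 1))
}

## degree-preserving rewiring of a directed binary graph (Maslov-Sneppen
## edge swaps via igraph); preserves every in- and out-degree exactly
.rewire_directed <- function(A, niter_per_edge = 10) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  m <- igraph::ecount(g)
  if (m < 2) stop("rewiring failed: graph too small to rewire")
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = niter_per_edge * m))
  as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
}

#' Normalized rich-club curve with rewiring nulls
#'
#' Computes the rich-club coefficient over a range of degree thresholds and
#' normalizes it by the mean coefficient of an ensemble of degree-preserving
#' rewired null networks; values above 1 indicate denser-than-chance
#' interconnection of high-degree nodes ("rich-club architecture").  The
#' operating threshold `k_star` is the smallest degree reaching 99% of the
#' maximal normalized coefficient, restricted to stretches where the curve
#' stays above 1 for at least two consecutive thresholds and at least five
#' nodes survive (noise guards against plateau jitter and the sparse tail).
#'
#' @param c a [connectome()].
#' @param k_range integer thresholds (default 0 to max degree - 1).
#' @param n_nulls number of rewired null networks (default 1000, minimum 10).
#' @param seed optional RNG seed.
#' @return object of class `rich_club`: `k`, `phi`, `phi_null_mean`,
#'   `phi_norm`, `k_star`, `n_nulls`.
#' @export
normalized_rich_club <- function(c, k_range = NULL, n_nulls = 1000,
                                 seed = NULL) {
  if (n_nulls < 10) stop("need at least 10 null networks")
  if (!is.null(seed)) set.seed(seed)
  bg <- .binary_digraph(c)
  k_range <- k_range %||% seq.int(0, max(bg$degree) - 1)
  phi_of <- function(A) {
    deg <- rowSums(A) + colSums(A)
    vapply(k_range, function(k) {
      keep <- deg > k
      Nk <- sum(keep)
      if (Nk < 2) return(NA_real_)
      sum(A[keep, keep]) / (Nk * (Nk - 1))
    }, numeric(1))
  }
  phi <- phi_of(bg$A)
  null_sum <- numeric(length(k_range))
  null_n <- numeric(length(k_range))
  for (r in seq_len(n_nulls)) {
    ph <- phi_of(.rewire_directed(bg$A))
    ok <- !is.na(ph)
    null_sum[ok] <- null_sum[ok] + ph[ok]
    null_n[ok] <- null_n[ok] + 1
  }
  null_mean <- ifelse(null_n > 0, null_sum / null_n, NA_real_)
  phi_norm <- phi / null_mean
  ## Operating threshold.  The normalized curve typically climbs to a
  ## plateau across the club's degree range and fluctuates wildly once only
  ## a handful of nodes survive, so k* is the smallest k reaching 99% of the
  ## maximal sustained exceedance, restricted to (i) runs of >= 2
  ## consecutive k above 1 (noise guard) and (ii) at least 5 survivors.
  Nk <- vapply(k_range, function(k) sum(bg$degree > k), numeric(1))
  above <- !is.na(phi_norm) & phi_norm > 1
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sustained <- runs$values & runs$lengths >= 2
  k_star <- NA_integer_
  if (any(sustained)) {
    in_run <- unlist(lapply(which(sustained), function(r) starts[r]:ends[r]))
    in_run <- in_run[Nk[in_run] >= 5]
    if (length(in_run)) {
      peak <- max(phi_norm[in_run])
      k_star <- k_range[in_run[phi_norm[in_run] >= 0.99 * peak][1]]
    }
  }
  structure(list(k = k_range, phi = phi, phi_null_mean = null_mean,
                 phi_norm = phi_norm, k_star = k_star, n_nulls = n_nulls),
            class = "rich_club")
}

#' @export
print.rich_club <- function(x, ...) {
  cat("Rich-club curve over k =", min(x$k), "..", max(x$k), "(",
      x$n_nulls, "nulls ): k* =", x$k_star, "\n")
  invisible(x)
}

#' Rich / feeder / local node classification
#'
#' Nodes whose total degree exceeds the operating threshold `k_star` are
#' `rich`; non-members with at least one link (either direction) to a rich
#' node are `feeder`; the rest are `local`.  If no rich club exists every node is `local` (with a
#' warning).
#'
#' @param c a [connectome()].
#' @param k_star degree threshold, typically from [normalized_rich_club()].
#' @return object of class `hub_classification`: factor `label` per region
#'   (levels rich/feeder/local) and `k_star`.
#' @export
classify_nodes <- function(c, k_star) {
  bg <- .binary_digraph(c)
  n <- length(bg$degree)
  lab <- rep("local", n)
  if (!is.na(k_star)) {
    rich <- which(bg$degree > k_star)
    lab[rich] <- "rich"
    if (length(rich)) {
      touches <- (rowSums(bg$A[, rich, drop = FALSE]) +
                    colSums(bg$A[rich, , drop = FALSE])) > 0
      lab[touches & lab != "rich"] <- "feeder"
    }
  }
  if (!any(lab == "rich"))
    warning("no rich club found; all regions labeled local")
  structure(list(label = factor(lab, levels = c("rich", "feeder", "local")),
                 k_star = k_star, degree = bg$degree,
                 region_labels = c$region_labels),
            class = "hub_classification")
}

#' @export
print.hub_classification <- function(x, ...) {
  cat("Hub classification at k* =", x$k_star, ":",
      sum(x$label == "rich"), "rich,",
      sum(x$label == "feeder"), "feeder,",
      sum(x$label == "local"), "local\n")
  invisible(x)
}

#' Diverse club membership
#'
#' The `size` regions with the highest time-averaged participation
#' coefficient; ties at the cut are broken by region index (ascending).
#'
#' @param ba per-region participation coefficients.
#' @param size club size (0..n).
#' @return integer vector of member indices.
#' @export
diverse_club <- function(ba, size) {
  stopifnot(size >= 0, size <= length(ba))
  if (size == 0) return(integer(0))
  sort(order(-ba, seq_along(ba))[seq_len(size)])
}

#' Realized neural gain from empirical input distributions
#'
#' The gain a region actually experiences is the sigmoid slope
#' `S'(v) = sigma S(v)(1 - S(v))` averaged over the empirical distribution
#' of its input — at most `sigma/4` (inputs concentrated at the sigmoid
#' center `m`), and smaller the further the input mass sits from `m`.
#' Estimated by histogram-weighted quadrature over each region's samples.
#'
#' @param V_inputs numeric vector, or time x region matrix of input samples
#'   (>= 100 samples per region).
#' @param sigma applied gain.
#' @param m sigmoid center (default 1.5).
#' @param n_bins histogram bins (default 100).
#' @return named numeric vector (one value per region) of class
#'   `realized_gain_map`.
#' @export
realized_gain <- function(V_inputs, sigma, m = 1.5, n_bins = 100) {
  V_inputs <- as.matrix(V_inputs)
  if (nrow(V_inputs) < 100)
    stop("need at least 100 input samples per region")
  slope <- function(v) sigma * sigmoid_activation(v, sigma, m) *
    (1 - sigmoid_activation(v, sigma, m))
  g <- apply(V_inputs, 2, function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(slope(rng[1]))
    br <- seq(rng[1], rng[2], length.out = n_bins + 1)
    h <- hist(v, breaks = br, plot = FALSE)
    sum(slope(h$mids) * h$counts) / length(v)
  })
  structure(setNames(as.numeric(g), colnames(V_inputs)),
            class = "realized_gain_map")
}

#' @export
print.realized_gain_map <- function(x, ...) {
  cat("Realized gain:", length(x), "regions, mean",
      signif(mean(x), 4), ", max", signif(max(x), 4), "\n")
  invisible(x)
}
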