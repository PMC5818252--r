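#' Consistency thresholding of a functional-connectivity stack
#'
#' Ranks edges by their variance across repeated estimates (ascending) and
#' retains the most consistent edges up to the requested density, so that
#' weak but reliable connections survive where a magnitude threshold would
#' drop them.  Retained edges carry the across-iteration mean weight.
#'
#' @param fc_stack an n x n x k array, or a list of [functional_connectivity()]
#'   results / symmetric matrices (k >= 2).
#' @param density fraction of the n(n-1)/2 possible edges to keep, in (0, 1].
#' @return symmetric n x n matrix; non-retained edges are 0.
#' @export
consistency_threshold <- function(fc_stack, density) {
  if (is.list(fc_stack))
    fc_stack <- simplify2array(lapply(fc_stack, function(f)
      if (inherits(f, "fc")) f$z else as.matrix(f)))
  stopifnot(length(dim(fc_stack)) == 3)
  k <- dim(fc_stack)[3]
  if (k < 2) stop("need at least 2 iterations for consistency thresholding")
  n <- dim(fc_stack)[1]
  if (!(density > 0 && density <= 1)) stop("density impossible: ", density)
  m <- round(density * n * (n - 1) / 2)
  if (m < 1) stop("density impossible: keeps no edges")
  mu <- apply(fc_stack, c(1, 2), mean)
  v <- apply(fc_stack, c(1, 2), stats::var)
  ut <- which(upper.tri(v))
  keep <- ut[order(v[ut], ut)[seq_len(m)]]
  out <- matrix(0, n, n)
  out[keep] <- mu[keep]
  out + t(out)
}

## modularity ("quality") matrix for signed networks, asymmetric
## normalization: positive term scaled by 1/v+, negative by 1/(v+ + v-)
.signed_quality_matrix <- function(W, resolution = 1) {
  W <- as.matrix(W)
  diag(W) <- 0
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  if (vp == 0 && vn == 0) stop("all-zero matrix: no structure to cluster")
  B <- matrix(0, nrow(W), ncol(W))
  if (vp > 0) B <- B + (Wp - resolution * outer(sp, sp) / vp) / vp
  if (vn > 0) B <- B - (Wn - resolution * outer(sn, sn) / vn) / (vp + vn)
  B
}

## quality of a partition = sum of B over same-module ordered pairs
.partition_quality <- function(B, memb) {
  sum(B[outer(memb, memb, "==")])
}

## one Louvain pass: sequential greedy moves with an incrementally
## maintained node-to-community strength table, then aggregation
.louvain_move_phase <- function(B, comm) {
  nn <- nrow(B)
  k <- max(comm)
  H <- matrix(0, nn, k); H[cbind(seq_len(nn), comm)] <- 1
  S <- B %*% H
  dB <- diag(B)
  repeat {
    moved <- FALSE
    for (i in sample.int(nn)) {
      cur <- comm[i]
      row <- S[i, ]
      row[cur] <- row[cur] - dB[i]      # exclude the self pair
      best <- which.max(row)
      if (best != cur && row[best] > row[cur] + 1e-12) {
        comm[i] <- best
        S[, cur] <- S[, cur] - B[, i]
        S[, best] <- S[, best] + B[, i]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  comm
}

.louvain_on_matrix <- function(B) {
  n <- nrow(B)
  memb <- seq_len(n)
  repeat {
    comm <- .louvain_move_phase(B, seq_len(nrow(B)))
    comm <- match(comm, unique(comm))
    if (max(comm) == nrow(B)) break     # nothing merged: done
    memb <- comm[memb]
    H <- matrix(0, length(comm), max(comm))
    H[cbind(seq_along(comm), comm)] <- 1
    B <- crossprod(H, B %*% H)
    if (nrow(B) == 1) break
  }
  match(memb, unique(memb))
}

#' Signed Louvain community detection
#'
#' Greedy move-and-aggregate maximization of the signed modularity, in which
#' within-module excess positive weight (normalized by the total positive
#' weight) is rewarded and within-module excess negative weight (normalized
#' by the total weight of both signs) is penalized.  The best of
#' `n_restarts` randomized restarts is returned.
#'
#' @param fc symmetric signed matrix (e.g. from [consistency_threshold()]),
#'   or an [functional_connectivity()] object.
#' @param resolution resolution parameter scaling the null expectation
#'   (default 1; larger values favor smaller modules).
#' @param n_restarts randomized restarts (default 10).
#' @param seed optional RNG seed.
#' @return object of class `partition`: `membership` (contiguous ids from
#'   1), `Q`, `resolution`, `n_modules`.
#' @export
louvain_signed <- function(fc, resolution = 1, n_restarts = 10, seed = NULL) {
  W <- if (inherits(fc, "fc")) fc$z else as.matrix(fc)
  if (!isSymmetric(unname(W), tol = 1e-8)) stop("matrix must be symmetric")
  if (!is.null(seed)) set.seed(seed)
  B <- .signed_quality_matrix(W, resolution)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    memb <- .louvain_on_matrix(B)
    q <- .partition_quality(B, memb)
    if (is.null(best) || q > best$Q + 1e-15)
      best <- list(membership = memb, Q = q)
  }
  structure(list(membership = best$membership, Q = best$Q,
                 resolution = resolution,
                 n_modules = max(best$membership)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("Partition:", x$n_modules, "modules, Q =", signif(x$Q, 5),
      "(resolution", x$resolution, ")\n")
  invisible(x)
}

#' Consensus partition over repeated Louvain runs
#'
#' Runs signed Louvain `n_runs` times, forms the module co-assignment
#' (agreement) matrix, and re-clusters the agreement matrix (centred on its
#' off-diagonal mean) until all runs coincide.  Deterministic for a fixed
#' seed.
#'
#' @inheritParams louvain_signed
#' @param n_runs number of randomized runs entering the agreement matrix
#'   (default 100).
#' @param max_iter safety cap on re-clustering rounds.
#' @return a `partition`; its `Q` is evaluated on the *original* matrix.
#' @export
consensus_partition <- function(fc, n_runs = 100, seed = NULL,
                                resolution = 1, max_iter = 20) {
  W <- if (inherits(fc, "fc")) fc$z else as.matrix(fc)
  if (!is.null(seed)) set.seed(seed)
  B0 <- .signed_quality_matrix(W, resolution)
  cluster_mat <- function(B) {
    vapply(seq_len(n_runs), function(r) .louvain_on_matrix(B),
           integer(nrow(B)))
  }
  runs <- cluster_mat(B0)
  for (it in seq_len(max_iter)) {
    same <- apply(runs, 2, function(m)
      identical(match(m, unique(m)), match(runs[, 1], unique(runs[, 1]))))
    if (all(same)) break
    n <- nrow(runs)
    D <- matrix(0, n, n)
    for (r in seq_len(ncol(runs))) D <- D + outer(runs[, r], runs[, r], "==")
    D <- D / ncol(runs)
    diag(D) <- 0
    Dc <- D - mean(D[upper.tri(D)])
    diag(Dc) <- 0
    runs <- cluster_mat(Dc)
  }
  memb <- match(runs[, 1], unique(runs[, 1]))
  structure(list(membership = memb,
                 Q = .partition_quality(B0, memb),
                 resolution = resolution, n_modules = max(memb)),
            class = "partition")
}

#' Participation coefficient over positive strengths
#'
#' \deqn{B_{Ai} = 1 - \sum_s (\kappa_{is}/\kappa_i)^2,} where
#' `kappa_is` is region i's positive connection strength into module s and
#' `kappa_i` its total positive strength: 0 when all links stay inside the
#' region's own module, approaching 1 when strength spreads evenly over all
#' modules.  Regions with no positive strength score 0.
#'
#' @param fc symmetric (signed) matrix or `fc` object; only positive weights
#'   are used.
#' @param partition a `partition` or a membership vector.
#' @return numeric vector of per-region coefficients (mean via `mean()`).
#' @export
participation_coefficient <- function(fc, partition) {
  W <- if (inherits(fc, "fc")) fc$z else as.matrix(fc)
  memb <- if (inherits(partition, "partition")) partition$membership
          else as.integer(partition)
  stopifnot(length(memb) == nrow(W))
  Wp <- pmax(W, 0); diag(Wp) <- 0
  k <- rowSums(Wp)
  H <- matrix(0, nrow(W), max(memb)); H[cbind(seq_len(nrow(W)), memb)] <- 1
  K <- Wp %*% H
  ba <- 1 - rowSums((K / pmax(k, .Machine$double.eps))^2)
  ba[k == 0] <- 0
  ba
}

#' Global efficiency of a weighted graph
#'
#' Mean inverse shortest-path length over ordered node pairs, with edge
#' lengths taken as the inverse of the (positive) connection weights;
#' disconnected pairs contribute zero.
#'
#' @param fc symmetric matrix or `fc` object; negative weights are ignored.
#' @return scalar in `[0, max weight]` (1 for a complete unit-weight graph).
#' @export
global_efficiency <- function(fc) {
  W <- if (inherits(fc, "fc")) fc$z else as.matrix(fc)
  Wp <- pmax(W, 0); diag(Wp) <- 0
  n <- nrow(Wp)
  if (n < 2) return(0)
  g <- igraph::graph_from_adjacency_matrix(Wp, mode = "undirected",
                                           weighted = TRUE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Mean clustering coefficient of the binarized graph
#'
#' Binarizes the graph (optionally keeping only the strongest positive edges
#' up to `density`) and averages the unweighted local clustering coefficient
#' — the proportion of closed triangles around each node — treating nodes
#' with fewer than two neighbors as 0.
#'
#' @param fc symmetric matrix or `fc` object.
#' @param density optional edge density for binarization; `NULL` keeps every
#'   non-zero edge (e.g. after [consistency_threshold()]).
#' @return scalar in `[0, 1]`.
#' @export
mean_clustering <- function(fc, density = NULL) {
  W <- if (inherits(fc, "fc")) fc$z else as.matrix(fc)
  diag(W) <- 0
  A <- .binarize(W, density)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(cc)
}

.binarize <- function(W, density = NULL) {
  n <- nrow(W)
  if (is.null(density)) return((W != 0) * 1)
  if (!(density > 0 && density <= 1)) stop("invalid density")
  m <- round(density * n * (n - 1) / 2)
  ut <- which(upper.tri(W))
  keep <- ut[order(-W[ut], ut)[seq_len(min(m, length(ut)))]]
  A <- matrix(0, n, n)
  A[keep] <- 1
  A + t(A)
}

#' Network communicability
#'
#' The communicability between two nodes is the weighted count of all walks
#' joining them, `C = e^A` for a binarized adjacency matrix `A` (computed by
#' scaling and squaring).  The scalar summary is the log10 of the mean
#' off-diagonal communicability.
#'
#' @param adjacency binarized symmetric matrix (any non-zero entry is taken
#'   as an edge), e.g. the thresholded edge set.
#' @return list with the full matrix `C` and `mean_log10`.
#' @export
communicability <- function(adjacency) {
  A <- (as.matrix(adjacency) != 0) * 1
  diag(A) <- 0
  C <- as.matrix(Matrix::expm(Matrix::Matrix(A, sparse = FALSE)))
  off <- C[row(C) != col(C)]
  list(C = C, mean_log10 = log10(mean(off)))
}

## Surprise of a partition on a binarized graph: minus the log cumulative
## hypergeometric probability of drawing at least the observed number of
## intra-module edges (in nats)
.surprise <- function(A, memb) {
  A <- (A != 0) * 1
  diag(A) <- 0
  n <- nrow(A)
  Fpairs <- n * (n - 1) / 2
  ut <- upper.tri(A)
  L <- sum(A[ut])
  same <- outer(memb, memb, "==")
  Fin <- sum(same[ut])
  lin <- sum(A[ut][same[ut]])
  if (L == 0) return(0)
  -stats::phyper(lin - 1, Fin, Fpairs - Fin, L, lower.tail = FALSE,
                 log.p = TRUE)
}

#' Choose a Louvain resolution by maximizing Surprise
#'
#' For every candidate resolution a consensus partition is computed and its
#' Surprise — minus the log cumulative hypergeometric probability of at
#' least the observed intra-module edge count, relative to random placement
#' of the same number of edges — is evaluated on the binarized graph.  The
#' resolution with maximal Surprise is returned; if every candidate yields a
#' single module the default 1.0 is returned with a warning.
#'
#' @param fc symmetric signed matrix.
#' @param resolutions positive candidate resolutions.
#' @param n_runs Louvain runs per consensus (default 20).
#' @param seed optional RNG seed.
#' @return list with `resolution` (the argmax), and a data.frame `table` of
#'   resolution, Surprise and module count.
#' @export
surprise_resolution <- function(fc, resolutions, n_runs = 20, seed = NULL) {
  W <- if (inherits(fc, "fc")) fc$z else as.matrix(fc)
  stopifnot(all(resolutions > 0))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(resolutions, function(r) {
    p <- consensus_partition(W, n_runs = n_runs, resolution = r)
    data.frame(resolution = r, surprise = .surprise(W, p$membership),
               n_modules = p$n_modules)
  })
  tab <- do.call(rbind, rows)
  if (all(tab$n_modules <= 1)) {
    warning("degenerate single-module partitions at every resolution; ",
            "returning the default 1.0")
    return(list(resolution = 1.0, table = tab))
  }
  list(resolution = tab$resolution[which.max(tab$surprise)], table = tab)
}

#' Time-averaged topology summary of a thresholded network
#'
#' Convenience wrapper applying the full integration/segregation suite to a
#' consistency-thresholded signed matrix: consensus signed-Louvain partition
#' (modularity Q and module count), mean participation coefficient, global
#' efficiency, mean clustering and communicability of the binarized kept
#' edge set.
#'
#' @param W_thr thresholded symmetric signed matrix.
#' @param n_runs Louvain runs for the consensus (default 100).
#' @param resolution Louvain resolution (default 1).
#' @param seed optional RNG seed.
#' @return object of class `topology_summary`.
#' @export
summarize_topology <- function(W_thr, n_runs = 100, resolution = 1,
                               seed = NULL) {
  part <- consensus_partition(W_thr, n_runs = n_runs, seed = seed,
                              resolution = resolution)
  ba <- participation_coefficient(W_thr, part)
  comm <- communicability(W_thr)
  structure(list(Q = part$Q, Q_inv = 1 / part$Q,
                 n_modules = part$n_modules,
                 membership = part$membership,
                 BA = ba, mean_BA = mean(ba),
                 global_efficiency = global_efficiency(W_thr),
                 mean_clustering = mean_clustering(W_thr),
                 mean_log10_communicability = comm$mean_log10),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("Topology: Q =", signif(x$Q, 4), "(", x$n_modules, "modules ),",
      "mean B_A =", signif(x$mean_BA, 4),
      ", efficiency =", signif(x$global_efficiency, 4),
      ", clustering =", signif(x$mean_clustering, 4),
      ", log10 communicability =",
      signif(x$mean_log10_communicability, 4), "\n")
  invisible(x)
}
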