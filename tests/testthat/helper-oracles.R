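## Independent brute-force oracles used across the suite.  These deliberately
## avoid the package's own code paths: plain loops and textbook formulas.

## all set partitions of 1..n as lists of membership vectors (Bell(8) = 4140)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_partitions(n - 1)
  out <- list()
  for (p in sub) {
    k <- max(p)
    for (c in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, c)
  }
  out
}

## signed modularity of a partition, straight from the defining formula:
## positive within-module excess over a strength null scaled by 1/v+,
## negative excess scaled by 1/(v+ + v-), summed over all ordered pairs
oracle_signed_q <- function(W, memb, resolution = 1) {
  n <- nrow(W)
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  diag(Wp) <- 0; diag(Wn) <- 0
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  q <- 0
  for (i in 1:n) for (j in 1:n) {
    if (memb[i] != memb[j]) next
    if (vp > 0) q <- q + (Wp[i, j] - resolution * sp[i] * sp[j] / vp) / vp
    if (vn > 0) q <- q - (Wn[i, j] - resolution * sn[i] * sn[j] / vn) / (vp + vn)
  }
  q
}

oracle_max_signed_q <- function(W, resolution = 1) {
  best <- -Inf
  for (p in all_partitions(nrow(W))) {
    q <- oracle_signed_q(W, p, resolution)
    if (q > best) best <- q
  }
  best
}

## participation coefficient by naive double loop over positive weights
oracle_participation <- function(W, memb) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in 1:n) {
    ki <- 0
    for (j in 1:n) if (j != i && W[i, j] > 0) ki <- ki + W[i, j]
    if (ki == 0) { out[i] <- 0; next }
    acc <- 0
    for (s in unique(memb)) {
      kis <- 0
      for (j in 1:n)
        if (j != i && memb[j] == s && W[i, j] > 0) kis <- kis + W[i, j]
      acc <- acc + (kis / ki)^2
    }
    out[i] <- 1 - acc
  }
  out
}

## global efficiency via Floyd-Warshall on lengths 1/w
oracle_efficiency <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in 1:n) for (j in 1:n)
    if (i != j && W[i, j] > 0) D[i, j] <- 1 / W[i, j]
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  acc <- 0
  for (i in 1:n) for (j in 1:n)
    if (i != j && is.finite(D[i, j])) acc <- acc + 1 / D[i, j]
  acc / (n * (n - 1))
}

## mean local clustering by exhaustive triple enumeration on a binary graph
oracle_clustering <- function(A) {
  n <- nrow(A)
  A <- (A != 0) * 1
  out <- numeric(n)
  for (i in 1:n) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) { out[i] <- 0; next }
    closed <- 0; total <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a >= b) next
      total <- total + 1
      if (A[nb[a], nb[b]] == 1) closed <- closed + 1
    }
    out[i] <- closed / total
  }
  mean(out)
}

## communicability by truncated power series sum_{k<=kmax} A^k / k!
oracle_communicability <- function(A, kmax = 20) {
  n <- nrow(A)
  C <- diag(n)
  P <- diag(n)
  for (k in 1:kmax) {
    P <- P %*% A / k
    C <- C + P
  }
  C
}

## directed rich-club coefficient by naive subgraph edge count
oracle_rich_club <- function(A, k) {
  deg <- rowSums(A != 0) + colSums(A != 0)
  keep <- which(deg > k)
  if (length(keep) < 2) return(NA_real_)
  e <- 0
  for (i in keep) for (j in keep) if (i != j && A[i, j] != 0) e <- e + 1
  e / (length(keep) * (length(keep) - 1))
}

## MTD by direct loops over pairs and windows
oracle_mtd <- function(x, w) {
  T <- nrow(x); n <- ncol(x)
  d <- apply(x, 2, diff)
  for (j in 1:n) d[, j] <- (d[, j] - mean(d[, j])) / sd(d[, j])
  Td <- nrow(d)
  nw <- Td - w + 1
  M <- array(0, c(n, n, nw))
  for (i in 1:n) for (j in 1:n) for (t in 1:nw)
    M[i, j, t] <- mean(d[t:(t + w - 1), i] * d[t:(t + w - 1), j])
  M
}

## pooled-variance two-sample t statistic, closed form
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

## small deterministic toy connectome used by several files
toy_connectome <- function(n = 6, seed = 42, density = 0.4) {
  set.seed(seed)
  w <- matrix(0, n, n)
  edges <- which(matrix(runif(n * n), n, n) < density & !diag(n))
  w[edges] <- runif(length(edges), 0.5, 2)
  l <- matrix(0, n, n)
  l[w > 0] <- runif(sum(w > 0), 10, 60)
  connectome(w, l, hemisphere = rep(c("left", "right"), length.out = n))
}
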