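two_cliques <- function(k = 4, w = 1) {
  n <- 2 * k
  W <- matrix(0, n, n)
  W[1:k, 1:k] <- w
  W[(k + 1):n, (k + 1):n] <- w
  diag(W) <- 0
  W
}

test_that("consistency thresholding keeps low-variance edges at density", {
  ## density 1: nothing removed, weights are the stack mean
  set.seed(3)
  st <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  for (k in 1:4) { st[, , k] <- st[, , k] + t(st[, , k]); diag(st[, , k]) <- 0 }
  full <- consistency_threshold(st, 1)
  expect_equal(full, apply(st, c(1, 2), mean))

  ## constant edge outlives a high-variance edge at 50% density
  st2 <- array(0, c(2 + 1, 3, 2))
  st2 <- array(0, c(3, 3, 2))
  st2[1, 2, ] <- st2[2, 1, ] <- c(0.5, 0.5)        # constant
  st2[1, 3, ] <- st2[3, 1, ] <- c(-2, 2)           # mean 0, high variance
  st2[2, 3, ] <- st2[3, 2, ] <- c(1, 1.8)
  thr <- consistency_threshold(st2, 1 / 3)
  expect_equal(thr[1, 2], 0.5)
  expect_equal(thr[1, 3], 0)
  expect_equal(thr[2, 3], 0)

  ## 10-iteration random stack equals the brute-force variance sort
  set.seed(7)
  n <- 8
  st3 <- array(rnorm(n * n * 10), c(n, n, 10))
  for (k in 1:10) { st3[, , k] <- st3[, , k] + t(st3[, , k]); diag(st3[, , k]) <- 0 }
  d <- 0.4
  thr3 <- consistency_threshold(st3, d)
  ut <- which(upper.tri(matrix(0, n, n)))
  vs <- apply(st3, c(1, 2), var)[ut]
  m <- round(d * n * (n - 1) / 2)
  expected_kept <- sort(ut[order(vs)][1:m])
  expect_equal(sort(which(upper.tri(thr3) & thr3 != 0)), expected_kept)

  expect_error(consistency_threshold(st3[, , 1, drop = FALSE], 0.5),
               "at least 2")
  expect_error(consistency_threshold(st3, 0), "density impossible")
})

test_that("signed Louvain attains the exhaustive-search maximum", {
  ## two positive 4-cliques: 2 modules at the global optimum
  W <- two_cliques(4)
  p <- louvain_signed(W, n_restarts = 20, seed = 1)
  expect_equal(p$n_modules, 2)
  expect_equal(sort(table(p$membership), decreasing = TRUE),
               sort(table(rep(1:2, each = 4)), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_equal(p$Q, oracle_max_signed_q(W), tolerance = 1e-12)

  ## a uniform positive clique has no divisible structure
  K <- matrix(1, 6, 6); diag(K) <- 0
  expect_equal(louvain_signed(K, n_restarts = 5, seed = 2)$n_modules, 1)

  ## negative inter-block edges cannot lower the two-block quality
  Wn <- W
  Wn[1:4, 5:8] <- -0.5
  Wn[5:8, 1:4] <- -0.5
  memb <- rep(1:2, each = 4)
  expect_gte(oracle_signed_q(Wn, memb), oracle_signed_q(W, memb))

  expect_error(louvain_signed(matrix(0, 4, 4)), "all-zero")
})

test_that("Louvain matches exhaustive search on random <= 8-node graphs", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(5:8, 1)
    W <- matrix(rnorm(n * n, 0.2, 1), n, n)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    p <- louvain_signed(W, n_restarts = 60, seed = seed)
    expect_equal(p$Q, oracle_max_signed_q(W), tolerance = 1e-10)
  }
})

test_that("consensus clustering is stable, deterministic and equivariant", {
  W <- two_cliques(4, w = 2)
  p1 <- consensus_partition(W, n_runs = 25, seed = 5)
  expect_equal(p1$n_modules, 2)
  expect_equal(p1$Q, oracle_max_signed_q(W), tolerance = 1e-12)
  p2 <- consensus_partition(W, n_runs = 25, seed = 5)
  expect_identical(p1$membership, p2$membership)

  ## label permutation: same partition up to relabeling
  set.seed(6)
  perm <- sample(8)
  Wp <- W[perm, perm]
  pp <- consensus_partition(Wp, n_runs = 25, seed = 5)
  expect_equal(adjusted_rand_index(pp$membership, p1$membership[perm]), 1)
})

test_that("participation coefficient matches Eq.-style direct summation", {
  ## all links inside own module -> 0
  W <- two_cliques(4)
  memb <- rep(1:2, each = 4)
  expect_equal(participation_coefficient(W, memb), rep(0, 8))

  ## equal strength to each of 4 modules -> 1 - 4 (1/4)^2 = 0.75
  W4 <- matrix(0, 9, 9)
  W4[1, c(2, 4, 6, 8)] <- 1; W4[c(2, 4, 6, 8), 1] <- 1
  memb4 <- c(1, 1, 2, 2, 3, 3, 4, 4, 1)
  expect_equal(participation_coefficient(W4, memb4)[1], 0.75)

  ## random weighted toy graph vs naive double loop
  set.seed(8)
  n <- 10
  Wr <- matrix(rnorm(n * n), n, n); Wr <- Wr + t(Wr); diag(Wr) <- 0
  mr <- sample(1:3, n, replace = TRUE)
  expect_equal(participation_coefficient(Wr, mr), oracle_participation(Wr, mr),
               tolerance = 1e-12)
})

test_that("global efficiency equals all-pairs shortest-path oracle", {
  K <- matrix(1, 5, 5); diag(K) <- 0
  expect_equal(global_efficiency(K), 1)
  expect_equal(global_efficiency(matrix(0, 2, 2)), 0)
  set.seed(9)
  W <- matrix(runif(25, 0, 2), 5, 5); W <- (W + t(W)) / 2; diag(W) <- 0
  W[W < 0.7] <- 0
  expect_equal(global_efficiency(W), oracle_efficiency(W), tolerance = 1e-12)
})

test_that("mean clustering counts closed triangles on the binarized graph", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(mean_clustering(tri), 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star[2:5, 1] <- 1
  expect_equal(mean_clustering(star), 0)
  set.seed(10)
  A <- matrix(rbinom(49, 1, 0.5), 7, 7); A <- 1 * ((A + t(A)) > 0); diag(A) <- 0
  expect_equal(mean_clustering(A), oracle_clustering(A), tolerance = 1e-12)
})

test_that("communicability equals the matrix exponential", {
  z <- communicability(matrix(0, 3, 3))
  expect_equal(z$C, diag(3))
  e2 <- communicability(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(e2$C[1, 2], sinh(1), tolerance = 1e-10)
  set.seed(12)
  A <- matrix(rbinom(36, 1, 0.4), 6, 6); A <- 1 * ((A + t(A)) > 0); diag(A) <- 0
  C <- communicability(A)$C
  expect_lt(max(abs(C - oracle_communicability(A))), 1e-8)
  expect_equal(communicability(A)$mean_log10,
               log10(mean(C[row(C) != col(C)])))
})

test_that("Surprise prefers the true division and drives resolution choice", {
  W <- two_cliques(5)
  memb2 <- rep(1:2, each = 5)
  s2 <- neurogain:::.surprise(W, memb2)
  s1 <- neurogain:::.surprise(W, rep(1, 10))
  expect_gt(s2, s1)
  ## random labels carry negligible surprise
  set.seed(13)
  sr <- replicate(20, neurogain:::.surprise(W, sample(memb2)))
  expect_lt(median(sr), s2 / 4)

  ## a single supplied resolution is returned unchanged
  out <- surprise_resolution(W, resolutions = 0.8, n_runs = 10, seed = 3)
  expect_equal(out$resolution, 0.8)
})

test_that("topology summary ties the metric suite together coherently", {
  W <- two_cliques(4)
  W[1, 5] <- W[5, 1] <- 0.2              # one weak bridge
  topo <- summarize_topology(W, n_runs = 20, seed = 4)
  expect_s3_class(topo, "topology_summary")
  expect_equal(topo$n_modules, 2)
  expect_gte(topo$mean_BA, 0)
  expect_lte(topo$mean_BA, 1)
  ## Q of the returned partition beats the all-in-one partition
  expect_gte(topo$Q, oracle_signed_q(W, rep(1, 8)))
  expect_equal(topo$Q_inv, 1 / topo$Q)
})
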