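hemis <- function(n) rep(c("left", "right"), length.out = n)

digraph_connectome <- function(A, len = 20) {
  l <- matrix(0, nrow(A), ncol(A))
  l[A > 0] <- len
  connectome(A, l, hemisphere = hemis(nrow(A)))
}

test_that("rich-club coefficient matches brute-force subgraph density", {
  ## complete directed graph saturates at 1 for every feasible k
  K <- matrix(1, 6, 6); diag(K) <- 0
  cK <- digraph_connectome(K)
  for (k in 0:9) expect_equal(rich_club_coefficient(cK, k), 1)

  ## K4 plus a pendant node: at k = 1 the pendant drops, leaving density 1
  A <- matrix(0, 5, 5)
  A[1:4, 1:4] <- 1; diag(A) <- 0
  A[5, 1] <- 1                               # pendant connected one-way
  cA <- digraph_connectome(A)
  expect_equal(rich_club_coefficient(cA, 2), 1)
  ## under-threshold graph: fewer than two survivors is undefined
  expect_true(is.na(rich_club_coefficient(cA, 6)))

  set.seed(19)
  R <- matrix(rbinom(100, 1, 0.3), 10, 10); diag(R) <- 0
  cR <- digraph_connectome(R)
  for (k in c(0, 2, 4, 6))
    expect_equal(rich_club_coefficient(cR, k), oracle_rich_club(R, k))
})

test_that("rewiring nulls preserve degrees and normalize ER to ~1", {
  set.seed(20)
  n <- 24
  A <- matrix(rbinom(n * n, 1, 0.25), n, n); diag(A) <- 0
  cc <- digraph_connectome(A)
  ## nulls preserve every in- and out-degree exactly
  A2 <- neurogain:::.rewire_directed(A)
  expect_equal(rowSums(A2), rowSums(A))
  expect_equal(colSums(A2), colSums(A))
  expect_false(identical(A2, A))

  ## an Erdos-Renyi-like graph has no rich club: phi_norm ~ 1
  rc <- normalized_rich_club(cc, k_range = 0:14, n_nulls = 1000, seed = 21)
  mid <- rc$k >= 2 & rc$k <= 10             # away from degenerate extremes
  expect_lt(max(abs(rc$phi_norm[mid] - 1), na.rm = TRUE), 0.1)
  expect_error(normalized_rich_club(cc, n_nulls = 5), "at least 10")
})

test_that("planted rich club is detected and classified", {
  cc <- synthetic_connectome(n = 76, rich_size = 22, density = 0.25, seed = 2)
  rc <- normalized_rich_club(cc, n_nulls = 200, seed = 22)
  expect_false(is.na(rc$k_star))
  high <- which(rc$k >= rc$k_star)
  expect_gt(max(rc$phi_norm[high], na.rm = TRUE), 1)

  cls <- classify_nodes(cc, rc$k_star)
  expect_equal(length(cls$label), 76)
  expect_true(all(levels(cls$label) == c("rich", "feeder", "local")))
  planted <- attr(cc, "planted_rich")
  sens <- mean(which(cls$label == "rich") %in% planted)
  expect_gt(sum(cls$label == "rich"), 0)
  expect_gt(sens, 0.5)    # most detected rich nodes are planted ones
})

test_that("degenerate classifications behave as documented", {
  K <- matrix(1, 5, 5); diag(K) <- 0
  cls <- classify_nodes(digraph_connectome(K), 1)
  expect_true(all(cls$label == "rich"))

  star <- matrix(0, 6, 6)
  star[1, 2:6] <- 1; star[2:6, 1] <- 1      # reciprocal star
  cs <- classify_nodes(digraph_connectome(star), 3)
  expect_equal(as.character(cs$label[1]), "rich")
  expect_true(all(cs$label[-1] == "feeder"))

  expect_warning(cls0 <- classify_nodes(digraph_connectome(K), NA),
                 "no rich club")
  expect_true(all(cls0$label == "local"))
})

test_that("diverse club is the top-k by participation with index ties", {
  ba <- c(0.9, 0.3, 0.7, 0.7, 0.1)
  expect_equal(diverse_club(ba, 5), 1:5)
  expect_equal(diverse_club(ba, 0), integer(0))
  expect_equal(diverse_club(ba, 2), c(1, 3))   # tie 3 vs 4 broken by index
  expect_equal(diverse_club(ba, 3), c(1, 3, 4))
  set.seed(23)
  b2 <- runif(30)
  expect_equal(diverse_club(b2, 7), sort(order(b2, decreasing = TRUE)[1:7]))
})

test_that("realized gain follows the sigmoid-slope quadrature", {
  ## inputs exactly at the center: slope sigma/4
  v <- matrix(1.5, 200, 2)
  expect_equal(as.numeric(realized_gain(v, sigma = 0.8)), rep(0.2, 2))
  ## zero gain: zero slope
  expect_equal(as.numeric(realized_gain(v, sigma = 0)), c(0, 0))
  ## uniform inputs on [m - 1, m + 1]: telescopes to (S(m+1) - S(m-1)) / 2
  set.seed(24)
  u <- matrix(runif(20000, 0.5, 2.5), 20000, 1)
  expected <- (sigmoid_activation(2.5, 1) - sigmoid_activation(0.5, 1)) / 2
  expect_equal(as.numeric(realized_gain(u, sigma = 1)), expected,
               tolerance = 0.01)
  expect_error(realized_gain(matrix(1, 10, 2), 1), "at least 100")

  ## bounded by sigma/4 and decreasing as inputs move away from the center
  g <- vapply(c(0, 0.5, 1, 2), function(sh) {
    set.seed(25)
    mean(realized_gain(matrix(rnorm(5000, 1.5 + sh, 0.3)), sigma = 1))
  }, numeric(1))
  expect_true(all(g <= 0.25 + 1e-12))
  expect_true(all(diff(g) < 0))
})
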