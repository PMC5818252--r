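test_that("sigmoid activation has the stated center, flat limit and slope", {
  expect_equal(sigmoid_activation(1.5, sigma = 3.7), 0.5)   # V = m
  expect_equal(sigmoid_activation(c(-5, 0, 99), sigma = 0), rep(0.5, 3))
  ## numeric derivative at V = m equals sigma / 4
  h <- 1e-6
  d <- (sigmoid_activation(1.5 + h, 1) - sigmoid_activation(1.5 - h, 1)) / (2 * h)
  expect_equal(d, 0.25, tolerance = 1e-8)
  expect_true(all(diff(sigmoid_activation(seq(-3, 5, 0.1), 2)) >= 0))
  ## saturates without overflow
  expect_equal(sigmoid_activation(1e6, 5), 1)
  expect_equal(sigmoid_activation(-1e6, 5), 0)
})

test_that("drift matches the model equations", {
  expect_equal(drift(0, 0, 0, 1), list(dV = 0, dW = 0))
  expect_equal(drift(1, 0, 0, 1), list(dV = 40, dW = -200))
  ## doubling gamma doubles only the current contribution to dV
  base <- drift(0.3, -0.1, 2, 0.5)
  dbl <- drift(0.3, -0.1, 2, 1.0)
  expect_equal(dbl$dV - base$dV, 20 * 0.5 * 2)
  expect_equal(dbl$dW, base$dW)
})

test_that("synaptic current equals the hand-unrolled delayed lookup", {
  ## single afferent, weight 2, delayed rate 0.5
  w <- matrix(c(0, 0, 2, 0), 2, 2)       # source 2 -> target 1
  d <- matrix(c(0, 0, 3, 0), 2, 2)
  hist <- matrix(0.25, 10, 2)
  hist[5, 2] <- 0.5
  I <- synaptic_current(hist, w, d, t = 8)   # 8 - 3 = 5
  expect_equal(I, c(1.0, 0))                 # no afferents for region 2

  ## 3-node chain with distinct delays vs explicit buffer unrolling
  w3 <- matrix(0, 3, 3)
  w3[2, 1] <- 1.5; w3[3, 2] <- 0.7; w3[1, 3] <- 2.2
  d3 <- matrix(0L, 3, 3)
  d3[2, 1] <- 2L; d3[3, 2] <- 5L; d3[1, 3] <- 1L
  set.seed(1)
  h3 <- matrix(runif(30), 10, 3)
  for (t in 6:10) {
    expected <- c(2.2 * h3[t - 1, 3], 1.5 * h3[t - 2, 1], 0.7 * h3[t - 5, 2])
    expect_equal(synaptic_current(h3, w3, d3, t), expected)
  }
  expect_error(synaptic_current(h3, w3, d3, t = 3), "history underrun")
})

test_that("local bifurcation scan reproduces the analytic structure", {
  scan <- local_bifurcation_scan(c(0, 1.70, 1.78, 5, 14.0, 14.5))
  ## zero drive: unique equilibrium at the origin, eigenvalues -10 +- i sqrt(3900)
  expect_equal(scan$V_star[1], 0)
  expect_equal(scan$eig_real[1], -10)
  expect_equal(scan$eig_imag[1], sqrt(3900))
  expect_equal(scan$regime[1], "stable focus")
  ## Hopf crossing near drive 1.74 at V* = 1 - sqrt(2/3)
  expect_equal(scan$regime[2], "stable focus")
  expect_equal(scan$regime[3], "limit cycle")
  vh <- 1 - sqrt(2 / 3)
  dh <- 10 * vh - 3 * vh^2 + vh^3
  expect_equal(dh, 1.740, tolerance = 1e-3)
  fine <- local_bifurcation_scan(c(dh - 1e-4, dh + 1e-4))
  expect_equal(fine$regime, c("stable focus", "limit cycle"))
  ## very large drive: stable again beyond V* = 1 + sqrt(2/3)
  expect_equal(scan$regime[5], "limit cycle")
  expect_equal(scan$regime[6], "stable focus")
  expect_gt(scan$V_star[6], 1 + sqrt(2 / 3))
})

test_that("integrator finds the origin, converges in dt, and is reproducible", {
  cc <- toy_connectome(n = 5, seed = 2)
  ## gamma = 0, no noise: every region decays to the origin equilibrium
  cfg0 <- sim_config(sigma = 1, gamma = 0, noise_std = 0, duration = 3,
                     transient = 0.5, dt = 0.001, sample_dt = 0.005)
  ts0 <- simulate_network(cfg0, cc, init = list(V = rep(0.1, 5),
                                                W = rep(-0.5, 5)))
  expect_lt(max(abs(ts0$V[nrow(ts0$V), ])), 1e-6)
  expect_lt(max(abs(ts0$W[nrow(ts0$W), ])), 1e-6)

  ## deterministic coupled run: dt vs dt/10 agree within O(dt)
  run_dt <- function(dt) {
    cfg <- sim_config(sigma = 1, gamma = 0.4, noise_std = 0, duration = 1,
                      transient = 0.9, dt = dt, sample_dt = 0.1)
    simulate_network(cfg, cc, init = list(V = seq(0.1, 0.5, 0.1),
                                          W = rep(0, 5)))
  }
  a <- run_dt(0.001)
  b <- run_dt(0.0001)
  expect_lt(max(abs(a$V[nrow(a$V), ] - b$V[nrow(b$V), ])), 0.05)

  ## identical seed => bit-identical trajectories
  cfg <- sim_config(sigma = 0.6, gamma = 0.3, duration = 2, transient = 0.5,
                    seed = 99)
  t1 <- simulate_network(cfg, cc)
  t2 <- simulate_network(cfg, cc)
  expect_identical(t1$V, t2$V)
  expect_identical(t1$W, t2$W)
})

test_that("stationary variance grows with the noise amplitude at gamma = 0", {
  cc <- toy_connectome(n = 4, seed = 5)
  v_at <- function(ns) {
    cfg <- sim_config(sigma = 0, gamma = 0, noise_std = ns, duration = 6,
                      transient = 1, seed = 17)
    var(as.vector(simulate_network(cfg, cc)$V))
  }
  vs <- vapply(c(0.25, 0.5, 1), v_at, numeric(1))
  expect_true(all(diff(vs) > 0))
})
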