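test_that("instantaneous phase tracks frequency and ignores linear trends", {
  dt <- 0.005
  t <- seq(0, 20, by = dt)
  f <- 8
  x <- sin(2 * pi * f * t)
  th <- instantaneous_phase(cbind(x, x))
  inc <- diff(th[, 1])
  inc <- inc[inc > -pi]                  # drop wrap-arounds
  expect_lt(abs(median(inc) - 2 * pi * f * dt) / (2 * pi * f * dt), 0.01)

  ## adding a ramp changes nothing: detrending removes it
  th2 <- instantaneous_phase(cbind(x + 3 * t, x))
  expect_equal(th2[, 1], th[, 1], tolerance = 1e-6)

  expect_error(instantaneous_phase(cbind(x, rep(2, length(t)))),
               "constant channel")
})

test_that("order parameter matches the closed-form examples", {
  ## all phases equal: rho = 1 at every time point
  th <- matrix(1.3, 50, 6)
  expect_equal(order_parameter(th)$rho, rep(1, 50))
  ## four symmetric phases cancel
  th4 <- matrix(c(0, pi / 2, pi, 3 * pi / 2), 10, 4, byrow = TRUE)
  expect_equal(order_parameter(th4)$rho, rep(0, 10), tolerance = 1e-12)
  ## two phases 0 and pi/2: |1 + i| / 2
  th2 <- matrix(c(0, pi / 2), 5, 2, byrow = TRUE)
  expect_equal(order_parameter(th2)$rho, rep(sqrt(2) / 2, 5))
  expect_error(order_parameter(matrix(0, 5, 1)), "at least 2 regions")
})

test_that("rho is bounded and invariant to region permutation", {
  set.seed(31)
  for (r in 1:5) {
    th <- matrix(runif(200 * 8, -pi, pi), 200, 8)
    rho <- order_parameter(th)$rho
    expect_true(all(rho >= 0 & rho <= 1))
    perm <- sample(8)
    expect_equal(order_parameter(th[, perm])$rho, rho)
  }
})

test_that("regime classification thresholds at 0.5, inclusive", {
  expect_equal(classify_regime(0.5), "synchronized")
  expect_equal(classify_regime(0.499), "unsynchronized")
  expect_equal(classify_regime(1), "synchronized")
  expect_error(classify_regime(1.2), "0, 1")
  expect_error(classify_regime(-0.1), "0, 1")
})

test_that("boundary detection interpolates the rho = 0.5 crossing", {
  sig <- seq(0, 1, 0.1)
  gam <- seq(0, 1, 0.25)
  ## step grid: flip at sigma = 0.5 in every gamma row
  step <- matrix(ifelse(sig < 0.5, 0.1, 0.9), length(sig), length(gam))
  b <- detect_boundary(step, sig, gam)
  expect_equal(b$sigma_crit, rep(0.45, 5), tolerance = 1e-10)  # interpolated
  ## linear ramp rho = sigma crosses exactly at 0.5
  ramp <- matrix(sig, length(sig), length(gam))
  br <- detect_boundary(ramp, sig, gam)
  expect_equal(br$sigma_crit, rep(0.5, 5))
  ## all-low grid: flagged no-crossing everywhere
  low <- matrix(0.2, length(sig), length(gam))
  bl <- detect_boundary(low, sig, gam)
  expect_true(all(!bl$sigma_valid))
  expect_true(all(is.na(bl$sigma_crit)))
})

test_that("boundary alignment recenters and recovers generative profiles", {
  sig <- seq(0, 1, 0.05)
  gam <- seq(0, 1, 0.1)
  prof <- function(x) 1 / (1 + exp(-25 * x))   # shared sigmoid profile
  shift <- 0.25 + 0.4 * gam                    # row-specific boundary
  rho <- sapply(gam, function(g) prof(sig - (0.25 + 0.4 * g)))
  b <- detect_boundary(rho, sig, gam)
  al <- align_to_boundary(rho, b, "sigma", range = c(0, 1))
  ok <- al$n == length(gam)                    # offsets covered by all rows
  expect_gt(sum(ok), 5)
  expect_equal(al$value[ok], prof(al$offset[ok]), tolerance = 0.02)

  ## translation invariance: same shift for every row leaves the curve alone
  rho2 <- sapply(gam, function(g) prof(sig - 0.3))
  b2 <- detect_boundary(rho2, sig, gam)
  al2 <- align_to_boundary(rho2, b2, "sigma", range = c(0, 1))
  one <- align_to_boundary(rho2[, 1, drop = FALSE],
                           detect_boundary(rho2[, 1, drop = FALSE], sig, 0),
                           "sigma", range = c(-1, 1))
  shared <- intersect(al2$offset[al2$n > 0], one$offset[one$n > 0])
  expect_equal(al2$value[match(shared, al2$offset)],
               one$value[match(shared, one$offset)], tolerance = 1e-10)
})

test_that("dwell-time tail fitting recovers Pareto and rejects exponential", {
  set.seed(41)
  ## synthetic Pareto(alpha = 2.5): MLE within [2.3, 2.7] at n = 1e4
  x <- runif(1e4)^(-1 / (2.5 - 1))
  fit <- pareto_tail_fit(x)
  expect_gt(fit$alpha, 2.3)
  expect_lt(fit$alpha, 2.7)

  ## exponential durations: likelihood ratio favors the exponential
  set.seed(42)
  fe <- pareto_tail_fit(rexp(5000, 1))
  expect_equal(fe$verdict, "exponential")
  expect_lt(fe$loglik_ratio, 0)

  ## excursions of a noisy series are measured in time units
  set.seed(43)
  s <- as.numeric(arima.sim(list(ar = 0.9), 5000)) / 3 + 0.5
  d <- dwell_time_tail(s, threshold = 0.5, dt = 0.1)
  expect_gt(length(d$durations), 50)
  expect_true(all(d$durations > 0))
  expect_true(is.finite(d$alpha))

  ## constant series has no complete excursions
  expect_error(dwell_time_tail(rep(1, 100)), "too few excursions")
})
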