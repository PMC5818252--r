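#' Simulation configuration
#'
#' Collects every knob of the delayed stochastic simulation.  Time is in
#' seconds throughout: with the rate constant 20 /s the isolated node is a
#' ~9.9 Hz damped oscillator, so the default step of 1 ms resolves each
#' period with ~100 steps.  `duration` is total simulated time including the
#' discarded `transient`.
#'
#' @param sigma neural gain (>= 0, swept over 0-1).
#' @param gamma excitability (>= 0, swept over 0-1).
#' @param m sigmoid center (default 1.5).
#' @param timescale rate constant in 1/s (fixed at 20 by the model).
#' @param noise_std amplitude of the additive white-noise processes on both
#'   state variables; increments have standard deviation
#'   `noise_std * sqrt(dt)` (default 1, i.e. unit-variance noise in model
#'   units).
#' @param dt integration step in seconds (default 0.001).
#' @param duration total simulated time in seconds (default 490: eight
#'   minutes of usable signal after the transient).
#' @param transient initial seconds discarded (default 10).
#' @param sample_dt sampling interval of the stored trajectories in seconds
#'   (default 0.005, i.e. 200 Hz — 20 samples per oscillation cycle).
#' @param conduction_speed axonal conduction speed in mm/ms (default 3).
#' @param seed integer RNG seed or NULL to leave the RNG state alone.
#' @param n_sessions independent repeats per parameter point (default 5).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(sigma = 0.5, gamma = 0.5, m = 1.5, timescale = 20,
                       noise_std = 1, dt = 0.001, duration = 490,
                       transient = 10, sample_dt = 0.005,
                       conduction_speed = 3, seed = NULL, n_sessions = 5) {
  stopifnot(sigma >= 0, gamma >= 0, dt > 0, duration > transient,
            transient >= 0, sample_dt >= dt, noise_std >= 0,
            conduction_speed > 0, n_sessions >= 1)
  structure(list(sigma = sigma, gamma = gamma, m = m, timescale = timescale,
                 noise_std = noise_std, dt = dt, duration = duration,
                 transient = transient, sample_dt = sample_dt,
                 conduction_speed = conduction_speed,
                 seed = if (!is.null(seed)) as.integer(seed),
                 n_sessions = as.integer(n_sessions)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: sigma =", x$sigma, ", gamma =", x$gamma,
      ", dt =", x$dt, "s, duration =", x$duration, "s (",
      x$transient, "s transient),", x$n_sessions, "session(s)\n")
  invisible(x)
}

#' Sampled neural trajectories
#'
#' @param V,W time x region matrices of membrane potential and recovery
#'   variable, sampled every `sample_dt` seconds after the transient.
#' @param sample_dt sampling interval (s).
#' @param I optional time x region matrix of synaptic currents at the same
#'   samples (stored by [simulate_network()]; used by the hemodynamic
#'   forward model).
#' @param config optional [sim_config()] provenance.
#' @return object of class `neural_ts`.
#' @export
neural_ts <- function(V, W, sample_dt, I = NULL, config = NULL) {
  V <- as.matrix(V); W <- as.matrix(W)
  stopifnot(all(dim(V) == dim(W)), sample_dt > 0)
  if (any(!is.finite(V)) || any(!is.finite(W)))
    stop("non-finite samples in neural time series")
  if (!is.null(I)) {
    I <- as.matrix(I)
    stopifnot(all(dim(I) == dim(V)))
  }
  structure(list(V = V, W = W, I = I, sample_dt = sample_dt,
                 config = config),
            class = "neural_ts")
}

#' @export
print.neural_ts <- function(x, ...) {
  cat("Neural time series:", nrow(x$V), "samples x", ncol(x$V),
      "regions at", 1 / x$sample_dt, "Hz (",
      nrow(x$V) * x$sample_dt, "s )\n")
  invisible(x)
}

## integer delay steps for the integrator: delays (ms) -> seconds -> steps,
## clamped to >= 1 step on existing connections so both Heun stages can be
## served from history
.delay_steps <- function(c, speed, dt) {
  d_ms <- compute_delays(c, speed)$delays
  steps <- round((d_ms / 1000) / dt)
  nz <- c$weights > 0
  if (any(steps[nz] < 1)) {
    warning(sum(steps[nz] < 1), " delay(s) shorter than one integration ",
            "step; rounded up to one step")
    steps[nz & steps < 1] <- 1
  }
  steps
}

#' Integrate the delayed stochastic oscillator network
#'
#' Stochastic Heun (predictor-corrector) integration of the coupled
#' two-dimensional oscillator network with axonal conduction delays and
#' additive Gaussian noise.  Delays are rounded to whole integration steps;
#' the firing-rate history is initialized at the initial state.  Identical
#' seeds give bit-identical output.
#'
#' @param cfg a [sim_config()] (its `seed`, if non-NULL, is applied before
#'   integration).
#' @param c a [connectome()].
#' @param init optional list with numeric vectors `V` and `W` of initial
#'   values (default: the origin equilibrium).
#' @return a [neural_ts()] with the post-transient trajectories.
#' @examples
#' cc <- synthetic_connectome(n = 10, rich_size = 3, density = 0.3, seed = 1)
#' ts <- simulate_network(sim_config(sigma = 0.5, gamma = 0.2, duration = 3,
#'                                   transient = 1, seed = 42), cc)
#' ts
#' @export
simulate_network <- function(cfg, c, init = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(c, "connectome"))
  n <- c$n_regions
  steps <- .delay_steps(c, cfg$conduction_speed, cfg$dt)
  src_idx <- vector("list", n); src_w <- vector("list", n)
  src_d <- vector("list", n)
  for (i in seq_len(n)) {
    js <- which(c$weights[i, ] > 0)
    src_idx[[i]] <- as.integer(js - 1L)
    src_w[[i]] <- c$weights[i, js]
    src_d[[i]] <- as.integer(steps[i, js])
  }
  max_d <- max(1L, unlist(src_d))
  n_steps <- round(cfg$duration / cfg$dt)
  transient_steps <- round(cfg$transient / cfg$dt)
  store_every <- max(1L, round(cfg$sample_dt / cfg$dt))
  v0 <- init$V %||% numeric(n)
  w0 <- init$W %||% numeric(n)
  stopifnot(length(v0) == n, length(w0) == n)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- .heun_delay_cpp(src_idx, src_w, src_d, n, cfg$gamma, cfg$sigma,
                         cfg$m, cfg$timescale, cfg$dt, n_steps,
                         transient_steps, store_every, cfg$noise_std,
                         v0, w0, max_d)
  neural_ts(res$V, res$W, store_every * cfg$dt, I = res$I, config = cfg)
}
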