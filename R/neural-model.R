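#' Sigmoid firing-rate activation
#'
#' Converts membrane potential to a normalized firing rate,
#' \deqn{S(V) = 1 / (1 + e^{-\sigma (V - m)}),}
#' where `sigma` is the neural gain (maximum slope `sigma/4`, attained at
#' `V = m`) and `m` centers the sigmoid on the typical input level.
#'
#' @param V membrane potential (vector or matrix).
#' @param sigma gain parameter (>= 0); `sigma = 0` gives a flat rate of 0.5.
#' @param m sigmoid center (default 1.5).
#' @return rates in (0, 1), same shape as `V`.
#' @export
sigmoid_activation <- function(V, sigma, m = 1.5) {
  1 / (1 + exp(-sigma * (V - m)))
}

#' Deterministic drift of the two-dimensional neural-mass oscillator
#'
#' Right-hand side of the local dynamics
#' \deqn{\dot V = 20 (W + 3V^2 - V^3 + \gamma I), \quad
#'       \dot W = 20 (-W - 10 V),}
#' with `V` the mean membrane potential, `W` the slow recovery variable and
#' `I` the afferent synaptic current scaled by the excitability `gamma`.
#' The rate constant (default 20 per second) sets the ~10 Hz intrinsic
#' timescale.
#'
#' @param V,W state variables (vectors of equal length).
#' @param I synaptic current per region.
#' @param gamma excitability.
#' @param timescale rate constant in 1/s (default 20).
#' @return list with elements `dV` and `dW`.
#' @export
drift <- function(V, W, I, gamma, timescale = 20) {
  list(dV = timescale * (W + 3 * V^2 - V^3 + gamma * I),
       dW = timescale * (-W - 10 * V))
}

#' Delayed synaptic current from a rate history
#'
#' Reference implementation of the coupling term
#' \deqn{I_i(t) = \sum_j A_{ij} S_j(t - \tau_{ij}),}
#' looking delayed firing rates up in an explicit history matrix.  The C++
#' integrator maintains the same quantity in a circular buffer; this function
#' exists for direct use and for cross-checking.
#'
#' @param rate_history T x n matrix; row `t` holds every region's firing rate
#'   at step `t`.
#' @param weights n x n matrix, row = target, column = source.
#' @param delay_steps n x n integer matrix of delays in whole steps
#'   (entries on zero-weight edges are ignored).
#' @param t current step index (1-based row of `rate_history`).
#' @return numeric vector of synaptic currents, one per target region.
#' @export
synaptic_current <- function(rate_history, weights, delay_steps, t) {
  n <- ncol(weights)
  stopifnot(ncol(rate_history) == n, all(dim(delay_steps) == dim(weights)))
  need <- max(delay_steps[weights > 0], 0)
  if (t - need < 1)
    stop("history underrun: step ", t, " needs ", need, " steps of history")
  I <- numeric(n)
  for (i in seq_len(n)) {
    js <- which(weights[i, ] > 0)
    if (length(js))
      I[i] <- sum(weights[i, js] *
                    rate_history[cbind(t - delay_steps[i, js], js)])
  }
  I
}

#' Local bifurcation structure of an isolated region
#'
#' For a grid of constant drives `gamma * I`, solves the equilibrium
#' conditions `W = -10 V` and `-10V + 3V^2 - V^3 + drive = 0` (the cubic is
#' strictly decreasing, so the equilibrium is unique), evaluates the Jacobian
#' `20 * [[6V - 3V^2, 1], [-10, -1]]`, and classifies the regime by the sign
#' of the largest real part: a stable focus below the Hopf bifurcation, a
#' limit cycle above it.  The Hopf drive is `10V* - 3V*^2 + V*^3` at
#' `V* = 1 - sqrt(2/3)`, about 1.740; a second Hopf at `V* = 1 + sqrt(2/3)`
#' (drive about 14.25) restores stability at very large drive.
#'
#' @param drive numeric vector of `gamma * I` values.
#' @param timescale rate constant (default 20).
#' @return data.frame with columns `drive`, `V_star`, `W_star`,
#'   `eig_real`, `eig_imag` (leading eigenvalue), `regime`.
#' @export
local_bifurcation_scan <- function(drive, timescale = 20) {
  stopifnot(all(is.finite(drive)))
  out <- lapply(drive, function(d) {
    ## roots of -V^3 + 3V^2 - 10V + d
    r <- polyroot(c(d, -10, 3, -1))
    vs <- Re(r[abs(Im(r)) < 1e-8 * (1 + abs(r))])
    v <- vs[which.min(abs(vs))]
    if (!length(v)) v <- Re(r[which.min(abs(Im(r)))])
    J <- timescale * matrix(c(6 * v - 3 * v^2, -10, 1, -1), 2, 2)
    ev <- eigen(J, only.values = TRUE)$values
    lead <- ev[which.max(Re(ev))]
    data.frame(drive = d, V_star = v, W_star = -10 * v,
               eig_real = Re(lead), eig_imag = abs(Im(lead)),
               regime = if (Re(lead) < 0) "stable focus" else "limit cycle")
  })
  do.call(rbind, out)
}
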