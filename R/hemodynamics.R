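#' Balloon-Windkessel hemodynamic parameters
#'
#' Canonical constants of the four-state hemodynamic model (vasodilatory
#' signal decay kappa, flow-dependent feedback gamma_f, venous transit time
#' tau, vessel stiffness alpha, resting oxygen extraction rho0, resting
#' venous volume fraction V0), with the standard published values as
#' defaults.
#'
#' @param kappa signal decay rate (1/s).
#' @param gamma_f feedback rate (1/s).
#' @param tau mean transit time (s).
#' @param alpha Grubb vessel stiffness exponent, in (0, 1).
#' @param rho0 resting oxygen extraction fraction.
#' @param V0 resting venous blood volume fraction.
#' @param TR sampling interval of the output BOLD signal (s).
#' @return object of class `hemodynamic_params`.
#' @export
hemodynamic_params <- function(kappa = 0.65, gamma_f = 0.41, tau = 0.98,
                               alpha = 0.32, rho0 = 0.34, V0 = 0.02,
                               TR = 0.72) {
  stopifnot(kappa > 0, gamma_f > 0, tau > 0, alpha > 0, alpha < 1,
            rho0 > 0, V0 > 0, TR > 0)
  structure(list(kappa = kappa, gamma_f = gamma_f, tau = tau, alpha = alpha,
                 rho0 = rho0, V0 = V0, TR = TR),
            class = "hemodynamic_params")
}

#' BOLD time series container
#'
#' @param signal time x region matrix of percent signal change.
#' @param TR sampling interval in seconds.
#' @return object of class `bold_series`.
#' @export
bold_series <- function(signal, TR) {
  signal <- as.matrix(signal)
  stopifnot(TR > 0)
  if (any(!is.finite(signal))) stop("non-finite BOLD samples")
  structure(list(signal = signal, TR = TR), class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat("BOLD series:", nrow(x$signal), "samples x", ncol(x$signal),
      "regions at TR =", x$TR, "s\n")
  invisible(x)
}

#' Balloon-Windkessel forward model
#'
#' Drives the four hemodynamic states (vasodilatory signal, inflow, venous
#' volume, deoxyhemoglobin) of each region with its neural activity and
#' returns percent BOLD signal change sampled at `TR`.  Constant-zero input
#' stays at the 0% baseline; a brief positive input produces the canonical
#' positive response followed by a post-stimulus undershoot.  Regions are
#' independent: identical input columns give identical output columns.
#'
#' For a [neural_ts()] from [simulate_network()] the default driving input
#' is the total membrane input `V + gamma I` — the local fluctuation plus
#' the afferent synaptic current.  Neurovascular coupling tracks synaptic
#' activity, and the afferent term is what lets slow collective (synchrony)
#' fluctuations reach the BOLD signal; the membrane potential alone is
#' nearly amplitude-blind at hemodynamic timescales because the fast
#' oscillation averages out in the slow hemodynamic states.
#'
#' @param neural a [neural_ts()] or a plain time x region matrix of neural
#'   activity.
#' @param p a [hemodynamic_params()].
#' @param dt input sampling interval in seconds; taken from `neural` when it
#'   is a `neural_ts`.
#' @param input for `neural_ts` input: `"drive"` (`V + gamma I`, default
#'   when currents were stored) or `"V"`.
#' @return a [bold_series()] sampled at `p$TR`.
#' @export
balloon_windkessel <- function(neural, p = hemodynamic_params(), dt = NULL,
                               input = c("drive", "V")) {
  input <- match.arg(input)
  if (inherits(neural, "neural_ts")) {
    z <- if (input == "drive" && !is.null(neural$I)) {
      gam <- neural$config$gamma %||% 1
      neural$V + gam * neural$I
    } else neural$V
    dt <- neural$sample_dt
  } else {
    z <- as.matrix(neural)
    if (is.null(dt)) stop("dt must be given for matrix input")
  }
  if (any(!is.finite(z))) stop("non-finite neural input")
  sample_every <- max(1L, round(p$TR / dt))
  b <- .balloon_windkessel_cpp(z, dt, p$kappa, p$gamma_f, p$tau, p$alpha,
                               p$rho0, p$V0, sample_every)
  bold_series(b, TR = sample_every * dt)
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain zero-phase filter with the squared magnitude response of
#' a 4th-order Butterworth band-pass (squared, as applied by forward-backward
#' filtering), removing DC exactly and leaving the passband within a few
#' percent of unit gain.  The default band (0.01-0.1 Hz) is the standard
#' resting-state BOLD band.
#'
#' @param b a [bold_series()].
#' @param low,high band edges in Hz; requires `0 < low < high < ` Nyquist.
#' @param order filter order (default 4).
#' @return a filtered [bold_series()].
#' @export
bandpass <- function(b, low = 0.01, high = 0.1, order = 4) {
  stopifnot(inherits(b, "bold_series"))
  nyq <- 1 / (2 * b$TR)
  if (!(low > 0 && low < high && high < nyq))
    stop("infeasible band [", low, ", ", high, "] Hz at TR = ", b$TR,
         " s (Nyquist ", nyq, " Hz)")
  x <- b$signal
  T <- nrow(x)
  f <- c(0, seq_len(T - 1)) / (T * b$TR)
  f <- pmin(f, 1 / b$TR - f)            # two-sided frequency axis
  gain <- ifelse(f <= 0, 0,
                 1 / (1 + (low / pmax(f, 1e-12))^(2 * order)) *
                   1 / (1 + (f / high)^(2 * order)))
  gain <- gain^2                        # zero-phase = forward + backward pass
  xf <- Re(stats::mvfft(stats::mvfft(x) * gain, inverse = TRUE)) / T
  bold_series(xf, b$TR)
}

#' Fisher-z functional connectivity
#'
#' Pearson correlation between all region pairs, Fisher r-to-z transformed
#' and clipped at `|z| <= zmax` so that perfectly correlated pairs stay
#' finite.  Constant regions are flagged and their edges set to zero.
#'
#' @param b a [bold_series()] (or time x region matrix).
#' @param zmax clip value for `|atanh(r)|` (default 6).
#' @return object of class `fc` with fields `z` (symmetric matrix, zero
#'   diagonal) and `n_samples`.
#' @export
functional_connectivity <- function(b, zmax = 6) {
  x <- if (inherits(b, "bold_series")) b$signal else as.matrix(b)
  T <- nrow(x)
  if (T < 3) stop("need at least 3 samples for functional connectivity")
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const))
    warning(sum(const), " constant region(s); their edges set to 0")
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0
  if (any(const)) { r[const, ] <- 0; r[, const] <- 0 }
  diag(r) <- 0
  z <- atanh(pmin(pmax(r, -1 + 1e-16), 1 - 1e-16))
  z <- pmin(pmax(z, -zmax), zmax)
  diag(z) <- 0
  structure(list(z = z, n_samples = T), class = "fc")
}

#' @export
print.fc <- function(x, ...) {
  ut <- upper.tri(x$z)
  cat("Functional connectivity:", nrow(x$z), "regions,", x$n_samples,
      "samples; mean z =", signif(mean(x$z[ut]), 4), "\n")
  invisible(x)
}
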