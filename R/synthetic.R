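#' Synthetic connectome with a planted rich club
#'
#' Generates a directed, weighted connectome that emulates the gross
#' statistics of a macaque-scale anatomical network: heavy-tailed (log-normal)
#' connection weights rescaled to unit mean, two balanced hemispheres with
#' down-weighted inter-hemispheric connection probability, tract lengths from
#' random 3-D coordinates with a hemispheric gap, and a planted set of
#' `rich_size` hub regions that are densely and mutually interconnected and
#' carry extra connections to the periphery.  The planted hub indices are
#' attached as `attr(x, "planted_rich")` so recovery can be scored.
#'
#' @param n number of regions (default 76, matching the macaque-scale
#'   connectome the pipeline emulates).
#' @param rich_size number of planted hub regions (default 22), split across
#'   hemispheres.
#' @param density fraction of the n(n-1) possible directed edges (default
#'   0.25); realized within one edge of the request.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param inter_hemisphere_factor multiplier (< 1) on the propensity of
#'   between-hemisphere edges (default 0.5).
#' @param p_rich inclusion probability for each directed edge inside the
#'   planted club (default 0.8).
#' @param feeder_boost propensity multiplier for edges with exactly one
#'   planted endpoint (default 2).
#' @return A [connectome()] with attribute `planted_rich`.
#' @examples
#' cc <- synthetic_connectome(n = 40, rich_size = 10, density = 0.2, seed = 1)
#' cc
#' @export
synthetic_connectome <- function(n = 76, rich_size = 22, density = 0.25,
                                 seed = 1, inter_hemisphere_factor = 0.5,
                                 p_rich = 0.8, feeder_boost = 2) {
  if (!(rich_size > 0 && rich_size < n)) stop("need 0 < rich_size < n")
  if (!(density > 0 && density < 1)) stop("need 0 < density < 1")
  set.seed(as.integer(seed))
  n_left <- ceiling(n / 2)
  hemi <- rep(c("left", "right"), c(n_left, n - n_left))
  rich <- c(seq_len(ceiling(rich_size / 2)),
            n_left + seq_len(floor(rich_size / 2)))
  is_rich <- seq_len(n) %in% rich

  m_target <- round(density * n * (n - 1))
  ## dense mutual interconnection of the planted club
  club_pairs <- which(outer(is_rich, is_rich, "&") & !diag(n) == 1)
  club_edges <- club_pairs[stats::runif(length(club_pairs)) < p_rich]
  if (length(club_edges) > m_target)
    stop("infeasible density for planted clique: the club alone needs ",
         length(club_edges), " edges but only ", m_target, " are allowed")

  ## sample the remaining edges with propensity weights
  prop <- matrix(1, n, n)
  prop[outer(is_rich, is_rich, "xor")] <- feeder_boost
  prop[outer(hemi, hemi, "!=")] <- prop[outer(hemi, hemi, "!=")] *
    inter_hemisphere_factor
  diag(prop) <- 0
  prop[club_edges] <- 0
  prop[outer(is_rich, is_rich, "&")] <- 0   # club pairs settled above
  cand <- which(prop > 0)
  extra <- sample(cand, m_target - length(club_edges), prob = prop[cand])
  edges <- c(club_edges, extra)

  w <- matrix(0, n, n)
  w[edges] <- stats::rlnorm(length(edges), 0, 1)
  w[edges] <- w[edges] / mean(w[edges])    # unit-mean weights

  ## spatially plausible tract lengths: macaque-scale mm coordinates (brain
  ## extent well under 100 mm so delays stay short relative to the ~100 ms
  ## oscillation period), hemispheres separated along x
  x <- ifelse(hemi == "left", stats::runif(n, -28, -4), stats::runif(n, 4, 28))
  y <- stats::runif(n, -32, 32)
  z <- stats::runif(n, 0, 28)
  lens <- as.matrix(stats::dist(cbind(x, y, z)))
  dimnames(lens) <- NULL

  labs <- paste0(ifelse(hemi == "left", "L", "R"),
                 unlist(lapply(table(factor(hemi, c("left", "right"))), seq_len)))
  out <- connectome(w, lens, labs, hemi)
  attr(out, "planted_rich") <- rich
  out
}

#' Surrogate BOLD with planted modular covariance
#'
#' Draws a multivariate Gaussian time series whose population correlation
#' matrix is block structured: `within_r` inside each of `n_modules` equal
#' blocks and `between_r` elsewhere.  Used to test the topology stages
#' without running any simulation; planted module labels are attached as
#' `attr(x, "planted_modules")`.
#'
#' @param n regions; `n_modules` equal-sized blocks (n divisible preferred,
#'   remainder spread over the first blocks).
#' @param n_modules number of blocks.
#' @param within_r,between_r population correlations inside/between blocks;
#'   requires `between_r < within_r < 1` and a positive-definite result.
#' @param T number of samples (> 1).
#' @param seed integer RNG seed.
#' @param TR nominal sampling interval in seconds (metadata only).
#' @return A [bold_series()] with attribute `planted_modules`.
#' @export
synthetic_modular_bold <- function(n = 20, n_modules = 4, within_r = 0.6,
                                   between_r = 0.05, T = 2000, seed = 1,
                                   TR = 0.72) {
  if (!(between_r < within_r && within_r < 1))
    stop("need between_r < within_r < 1")
  if (T < 2) stop("need at least 2 samples")
  set.seed(as.integer(seed))
  mod <- sort(rep_len(seq_len(n_modules), n))
  R <- matrix(between_r, n, n)
  same <- outer(mod, mod, "==")
  R[same] <- within_r
  diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e)
    stop("requested block covariance is not positive definite"))
  x <- matrix(stats::rnorm(T * n), T, n) %*% ch
  out <- bold_series(x, TR = TR)
  attr(out, "planted_modules") <- mod
  out
}
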