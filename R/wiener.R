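## Wiener first-passage-time distribution: density, absorption probability
## and random sampling.

#' Wiener first-passage-time log density
#'
#' Log density of the two-boundary Wiener diffusion first-passage time under
#' the signed-RT convention: positive `rt` denotes absorption at the upper
#' boundary, negative `rt` at the lower boundary.  Evaluation switches
#' between the small-time and large-time series expansions, with term counts
#' chosen for an absolute truncation tolerance of 1e-9.
#'
#' @param rt signed response times in seconds (vector).
#' @param alpha boundary separation (> 0).
#' @param tau non-decision time in seconds (>= 0).
#' @param z relative starting point in (0, 1); `z > 0.5` biases towards the
#'   upper boundary.
#' @param v drift rate.
#' @param log if `TRUE` (default) return log density.
#' @return vector of (log) densities; `-Inf` (or 0) where `|rt| <= tau`.
#' @export
dwiener <- function(rt, alpha, tau, z, v, log = TRUE) {
  stopifnot(all(alpha > 0), all(tau >= 0), all(z > 0), all(z < 1))
  out <- .wiener_logpdf_cpp(as.numeric(rt), as.numeric(alpha),
                            as.numeric(tau), as.numeric(z), as.numeric(v))
  if (log) out else exp(out)
}

#' Probability of absorption at the upper boundary
#'
#' Closed-form absorption probability of the Wiener diffusion: the
#' probability that evidence reaches the upper boundary before the lower
#' one.  Equals `z` at zero drift.
#'
#' @inheritParams dwiener
#' @return vector of probabilities.
#' @export
wiener_upper_prob <- function(alpha, z, v) {
  stopifnot(all(alpha > 0), all(z > 0), all(z < 1))
  .wiener_upper_prob_cpp(as.numeric(alpha), as.numeric(z), as.numeric(v))
}

#' Sample Wiener first-passage times
#'
#' Draws signed first-passage samples (boundary and RT jointly).  The
#' default `"inverse"` method samples the boundary from its closed-form
#' absorption probability and the conditional passage time by numerical
#' inversion of the series-evaluated CDF on a fine grid; `"euler"` simulates
#' the diffusion path with an Euler-Maruyama scheme of step `dt` (accuracy
#' improves as `sqrt(dt)`, at proportional cost).
#'
#' @inheritParams dwiener
#' @param n number of draws.
#' @param method `"inverse"` (series-based, effectively exact) or
#'   `"euler"` (path simulation).
#' @param dt Euler time step in seconds.
#' @param t_max give up (return `NA`) if no absorption by this decision time.
#' @param grid_n grid resolution for the inverse-CDF method.
#' @return numeric vector of signed RTs: `tau + decision time`, negated for
#'   lower-boundary absorptions.  All finite values satisfy `|rt| > tau`.
#' @export
rwiener <- function(n, alpha, tau, z, v, method = c("inverse", "euler"),
                    dt = 1e-4, t_max = 30, grid_n = 4096L) {
  method <- match.arg(method)
  stopifnot(n >= 0, alpha > 0, tau >= 0, z > 0, z < 1)
  if (n == 0) return(numeric(0))
  if (method == "euler") {
    return(.wiener_sample_euler_cpp(as.integer(n), alpha, tau, z, v, dt,
                                    t_max))
  }
  p_up <- wiener_upper_prob(alpha, z, v)
  upper <- stats::runif(n) < p_up
  out <- numeric(n)
  for (side in c(TRUE, FALSE)) {
    m <- sum(upper == side)
    if (m == 0) next
    out[upper == side] <- .rwiener_inverse_one(m, alpha, z, v, side, t_max,
                                               grid_n)
  }
  sgn <- ifelse(upper, 1, -1)
  sgn * (tau + out)
}

## inverse-CDF sampling of the decision time conditional on one boundary
.rwiener_inverse_one <- function(m, alpha, z, v, upper, t_max, grid_n) {
  tt <- seq(0, t_max, length.out = grid_n)[-1]
  srt <- if (upper) tt else -tt
  dens <- exp(.wiener_logpdf_cpp(srt, alpha, 0, z, v))
  # trapezoid cumulative mass over the grid
  dt <- tt[2] - tt[1]
  cum <- cumsum((dens + c(0, dens[-length(dens)])) / 2 * dt)
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate passage-time distribution")
  u <- stats::runif(m) * total
  idx <- findInterval(u, cum) + 1L
  idx <- pmin(idx, length(tt))
  lo <- c(0, cum)[idx]
  w <- (u - lo) / pmax(cum[idx] - lo, .Machine$double.eps)
  t_lo <- c(0, tt)[idx]
  t_lo + w * (tt[idx] - t_lo)
}
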