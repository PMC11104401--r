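## WAIC model comparison.

#' Widely applicable information criterion
#'
#' `WAIC = -2 * (lppd - p_waic)` from a draws x trials matrix of pointwise
#' log-likelihoods: `lppd` is the summed log of pointwise posterior mean
#' likelihoods (computed stably in log space) and the effective number of
#' parameters `p_waic` is the summed pointwise posterior variance of the
#' log-likelihood.  Lower WAIC indicates superior fit.
#'
#' @param pointwise_loglik draws x trials matrix, or a `ctxfit` (whose
#'   stored matrix is used).
#' @return list with `waic`, `p_waic`, `lppd`, a per-trial `pointwise`
#'   data.frame and the standard error `se` of WAIC.
#' @export
compute_waic <- function(pointwise_loglik) {
  if (inherits(pointwise_loglik, "ctxfit"))
    pointwise_loglik <- pointwise_loglik$pointwise_loglik
  ll <- as.matrix(pointwise_loglik)
  if (nrow(ll) < 1 || any(!is.finite(ll)))
    stop("pointwise log-likelihoods must be finite (>= 1 draw)")
  nd <- nrow(ll)
  ## column-wise log-sum-exp
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx))))
  p_i <- apply(ll, 2, stats::var)
  if (nd == 1) p_i <- rep(0, ncol(ll))
  waic_i <- -2 * (lppd_i - p_i)
  list(waic = sum(waic_i), p_waic = sum(p_i), lppd = sum(lppd_i),
       se = sqrt(ncol(ll) * stats::var(waic_i)),
       pointwise = data.frame(lppd = lppd_i, p_waic = p_i, waic = waic_i))
}

#' Compare fitted models by WAIC
#'
#' Ranks fits of the identical trial set (enforced via the data
#' fingerprint) by ascending WAIC, with differences to the best model and
#' the standard error of each difference from the pointwise contributions.
#'
#' @param ... two or more `ctxfit` objects (or a single list of them).
#' @return data.frame of class `ctx_model_comparison`, sorted by WAIC.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "ctxfit"))
    fits <- fits[[1]]
  stopifnot(all(vapply(fits, inherits, TRUE, "ctxfit")))
  fps <- vapply(fits, `[[`, "", "fingerprint")
  if (length(unique(fps)) != 1)
    stop("fits were not computed on the identical trial set ",
         "(mismatched data fingerprints)")
  names(fits) <- vapply(fits, `[[`, "", "model")
  w <- lapply(fits, compute_waic)
  ord <- order(vapply(w, `[[`, 0, "waic"))
  best <- w[[ord[1]]]
  rows <- lapply(ord, function(i) {
    d_i <- w[[i]]$pointwise$waic - best$pointwise$waic
    data.frame(model = names(fits)[i], waic = w[[i]]$waic,
               p_waic = w[[i]]$p_waic, se = w[[i]]$se,
               d_waic = w[[i]]$waic - best$waic,
               d_se = sqrt(length(d_i) * stats::var(d_i)),
               converged = fits[[i]]$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ctx_model_comparison", "data.frame")
  out
}

#' @export
print.ctx_model_comparison <- function(x, digits = 1, ...) {
  y <- x; class(y) <- "data.frame"
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y)
  invisible(x)
}
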