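## Prior specification for the hierarchical models.

#' Default prior specification for a model
#'
#' Builds the package-default prior scheme: uniform priors over numerically
#' plausible ranges for baseline group-level means, zero-centered Gaussian
#' priors for all context-shift group-level means, and Gamma(0.001, 0.001)
#' priors on group-level precisions.  The uniform ranges are package
#' defaults, declared here rather than asserted as canonical; sensitivity to
#' them should be reported for results-critical comparisons.
#'
#' @param model a registered model name, see [list_models()].
#' @param shift_sd optional named numeric vector overriding the prior SD of
#'   individual shift means (names are baseline parameter names).
#' @return an object of class `ctx_priors`: a named list with one entry per
#'   free parameter, each holding a `baseline` (or `shift`) distribution and
#'   the common `precision` prior.
#' @export
ctx_priors <- function(model, shift_sd = NULL) {
  info <- model_info(model)
  ranges <- .par_range()
  out <- list()
  for (p in info$pars) {
    r <- ranges[[p]]
    out[[p]] <- list(kind = "baseline",
                     dist = list(dist = "uniform", lo = r[1], hi = r[2]))
  }
  for (p in info$pars) {
    sd <- if (!is.null(shift_sd) && p %in% names(shift_sd))
      shift_sd[[p]] else .shift_prior_sd(p)
    out[[.shift_name(p)]] <- list(kind = "shift",
                                   dist = list(dist = "normal", mean = 0,
                                               sd = sd))
  }
  structure(list(model = model, pars = out,
                 precision = list(shape = 0.001, rate = 0.001)),
            class = "ctx_priors")
}

#' @export
print.ctx_priors <- function(x, ...) {
  cat("Prior specification for model '", x$model, "'\n", sep = "")
  for (nm in names(x$pars)) {
    d <- x$pars[[nm]]$dist
    if (d$dist == "uniform")
      cat(sprintf("  %-12s mean ~ Uniform(%g, %g)\n", nm, d$lo, d$hi))
    else
      cat(sprintf("  %-12s mean ~ Normal(%g, %g)\n", nm, d$mean, d$sd))
  }
  cat(sprintf("  group precisions ~ Gamma(%g, %g)\n",
              x$precision$shape, x$precision$rate))
  invisible(x)
}

.check_priors <- function(priors, info) {
  if (!inherits(priors, "ctx_priors"))
    stop("'priors' must be built with ctx_priors()", call. = FALSE)
  missing <- setdiff(info$all_pars, names(priors$pars))
  extra <- setdiff(names(priors$pars), info$all_pars)
  if (length(missing) || length(extra))
    stop("prior/model mismatch for '", info$model, "': missing [",
         paste(missing, collapse = ", "), "], extraneous [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  for (nm in names(priors$pars)) {
    k <- priors$pars[[nm]]
    if (k$kind == "shift" && k$dist$dist == "normal" &&
        !isTRUE(all.equal(k$dist$mean, 0)))
      stop("shift prior for ", nm, " must be centered at 0", call. = FALSE)
  }
  invisible(TRUE)
}
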