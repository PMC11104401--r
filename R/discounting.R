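## Intertemporal-choice model components: hyperbolic valuation, choice
## rules, RT preprocessing and the model log-likelihoods.

#' Hyperbolic subjective value of the larger-later option
#'
#' `A / (1 + exp(k_log + s_k * I) * D)`: the discount rate lives in
#' log-space and is shifted additively by `s_k` in the gambling context
#' (`I = 1`).
#'
#' @param A larger-later amount (euro).
#' @param D delay in days (>= 0).
#' @param k_log log discount rate (log 1/days).
#' @param s_k context shift of the log discount rate.
#' @param I context indicator, 0 (neutral) or 1 (gambling).
#' @return subjective value on the euro scale.
#' @export
subjective_value <- function(A, D, k_log, s_k = 0, I = 0) {
  if (any(D < 0)) stop("negative delay")
  A / (1 + exp(k_log + s_k * I) * D)
}

#' Softmax probability of choosing the larger-later option
#'
#' Logistic in `(beta + s_beta * I) * (sv_ll - 20)`; the smaller-sooner
#' subjective value is fixed at its 20 euro face value.
#'
#' @param sv_ll subjective value of the larger-later option.
#' @param beta inverse temperature (euro^-1).
#' @param s_beta context shift of `beta`.
#' @inheritParams subjective_value
#' @export
softmax_ll_probability <- function(sv_ll, beta, s_beta = 0, I = 0) {
  stats::plogis((beta + s_beta * I) * (sv_ll - .dd_ss))
}

#' Linear trial-wise drift rate
#'
#' `(v_coeff + s_vcoeff * I) * (sv_ll - 20)`: the scaled subjective value
#' difference; zero at indifference, negative when the smaller-sooner option
#' dominates.
#'
#' @param sv_ll subjective value of the larger-later option.
#' @param v_coeff drift scaling coefficient.
#' @param s_vcoeff context shift of `v_coeff`.
#' @inheritParams subjective_value
#' @export
drift_linear <- function(sv_ll, v_coeff, s_vcoeff = 0, I = 0) {
  (v_coeff + s_vcoeff * I) * (sv_ll - .dd_ss)
}

#' Sigmoid drift-rate transform
#'
#' `S(m) = 2 * V / (1 + exp(-m)) - V` with asymptote
#' `V = v_max + s_vmax * I`: an odd, bounded squashing of the linear drift
#' input, capturing saturating value sensitivity of RTs.
#'
#' @param m unbounded drift input (e.g. from [drift_linear()]).
#' @param v_max drift asymptote (> 0 effectively).
#' @param s_vmax context shift of `v_max`.
#' @inheritParams subjective_value
#' @export
drift_sigmoid <- function(m, v_max, s_vmax = 0, I = 0) {
  V <- v_max + s_vmax * I
  if (any(V <= 0)) stop("nonpositive effective drift asymptote")
  2 * V / (1 + exp(-m)) - V
}

#' Preprocess intertemporal-choice response times
#'
#' Applies the signed-RT convention (smaller-sooner RTs negated) and the
#' percentile trim: per participant, the `trim` fastest and `trim` slowest
#' fraction of trials (by absolute RT, per-tail counts rounded down, ties
#' resolved by trial order) are removed.
#'
#' @param trials data.frame with at least `subject`, `choice` (1 = LL) and
#'   `rt` (positive seconds).
#' @param trim per-tail trim fraction (default 0.025).
#' @return the retained trials with an added signed `rt` column (original
#'   raw RTs preserved as `rt_raw`).
#' @export
preprocess_discounting_rts <- function(trials, trim = 0.025) {
  if (nrow(trials) == 0) stop("empty trial data")
  stopifnot(all(c("subject", "choice", "rt") %in% names(trials)))
  if (any(trials$rt <= 0, na.rm = TRUE))
    stop("raw RTs must be positive; signing is applied here")
  keep <- unlist(lapply(split(seq_len(nrow(trials)), trials$subject),
                        function(idx) {
    k <- floor(length(idx) * trim)
    if (k == 0) return(idx)
    ord <- idx[order(trials$rt[idx])]       # ties: earlier trial trimmed first
    ord[seq(k + 1L, length(ord) - k)]
  }), use.names = FALSE)
  out <- trials[sort(keep), , drop = FALSE]
  out$rt_raw <- out$rt
  out$rt <- ifelse(out$choice == 1, out$rt, -out$rt)
  rownames(out) <- NULL
  out
}

#' Pointwise log-likelihood of an intertemporal-choice model
#'
#' Evaluates the per-trial log-likelihood of one subject's (or a pooled)
#' trial table under the requested variant.  `softmax` uses choices only;
#' the DDM variants use the signed RTs from
#' [preprocess_discounting_rts()].  `ddm0` has a context-shifted but
#' value-independent drift; `ddm_lin` and `ddm_s` derive the trial drift
#' from the subjective value difference (linearly, resp. through the
#' sigmoid transform).
#'
#' @param model `"softmax"`, `"ddm0"`, `"ddm_lin"` or `"ddm_s"`.
#' @param params named list or vector of the model's parameters (baselines
#'   and, optionally, `s_` shifts; missing shifts default to 0).
#' @param trials data.frame with `ll_amount`, `delay`, `context`, `choice`
#'   and (for DDMs) signed `rt`.
#' @return numeric vector of per-trial log-likelihoods.
#' @export
discounting_loglik <- function(model, params, trials) {
  info <- model_info(model)
  if (info$task != "discounting") stop("'", model, "' is not a discounting model")
  theta <- .theta_vector(params, info)
  rt <- if ("rt" %in% names(trials)) as.numeric(trials$rt) else
    rep(NA_real_, nrow(trials))
  .loglik_discounting_cpp(info$id, theta,
                          as.numeric(trials$ll_amount),
                          as.numeric(trials$delay),
                          as.integer(trials$context),
                          as.integer(trials$choice), rt)
}

## named params (list/vector) -> ordered theta vector c(baselines, shifts)
.theta_vector <- function(params, info) {
  p <- unlist(params)
  miss <- setdiff(info$pars, names(p))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  shifts <- .shift_name(info$pars)
  full <- c(p[info$pars],
            vapply(shifts, function(s) if (s %in% names(p)) p[[s]] else 0,
                   0))
  names(full) <- info$all_pars
  as.numeric(full)
}
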