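## Two-step task model components: the modified hybrid MF/MB learner
## (per-stage learning rates, decay of unchosen values, perseveration) and
## its softmax / drift-diffusion choice rules.  These R-level operations are
## the reference implementation; the fitted likelihoods run the same
## recursion in compiled code.

#' Initial Q state
#'
#' All model-free values start at the rescaled walk mean 0.5; rewards are
#' assumed rescaled from points (0-100) to \[0, 1\].
#'
#' @return a list with `q_mf_s1` (2 values), `q_mf_s2` (2 states x 2
#'   actions) and `last_s1_action` (`NA` before the first trial).
#' @export
qstate_init <- function() {
  list(q_mf_s1 = c(0.5, 0.5),
       q_mf_s2 = matrix(0.5, 2, 2,
                        dimnames = list(state = NULL, action = NULL)),
       last_s1_action = NA_integer_)
}

.eff <- function(params, name, I) {
  s <- paste0("s_", name)
  base <- params[[name]]
  shift <- if (!is.null(params[[s]])) params[[s]] else 0
  base + shift * I
}

#' Model-free value update
#'
#' Stage-2 prediction error `r - Q_S2(chosen)` updates the chosen stage-2
#' value with the stage-2 learning rate; the stage-1 error (pre-update
#' stage-2 value minus the chosen stage-1 value) and the stage-2 error both
#' feed the chosen stage-1 value (eligibility trace fixed to 1).
#'
#' @param state a Q state from [qstate_init()].
#' @param trial list or one-row data.frame with `s1_action`, `s2_state`,
#'   `s2_action` (all in 1:2) and `reward` in \[0, 1\].
#' @param params named list with `eta1`, `eta2` (and optional shifts).
#' @param I context indicator.
#' @return the updated state (with `last_s1_action` set).
#' @export
mf_update <- function(state, trial, params, I = 0) {
  eta1 <- .eff(params, "eta1", I)
  eta2 <- .eff(params, "eta2", I)
  if (eta1 < 0 || eta1 > 1 || eta2 < 0 || eta2 > 1)
    stop("effective learning rates must lie in [0, 1]")
  a1 <- trial$s1_action; st <- trial$s2_state; a2 <- trial$s2_action
  delta2 <- trial$reward - state$q_mf_s2[st, a2]
  delta1 <- state$q_mf_s2[st, a2] - state$q_mf_s1[a1]
  state$q_mf_s2[st, a2] <- state$q_mf_s2[st, a2] + eta2 * delta2
  state$q_mf_s1[a1] <- state$q_mf_s1[a1] + eta1 * delta1 + eta2 * delta2
  state$last_s1_action <- a1
  state
}

#' Model-based stage-1 values
#'
#' Bellman lookahead: each stage-1 action's value is the transition-weighted
#' maximum of the two stage-2 states' model-free values.
#'
#' @param state a Q state.
#' @param p_common probability of the common transition.
#' @return length-2 vector of model-based values (action 1 prefers state 1).
#' @export
mb_values <- function(state, p_common = 0.7) {
  mx <- apply(state$q_mf_s2, 1, max)
  c(p_common * mx[1] + (1 - p_common) * mx[2],
    p_common * mx[2] + (1 - p_common) * mx[1])
}

#' Decay unchosen values toward the walk mean
#'
#' Every unchosen value at all three stages relaxes toward 0.5:
#' `Q <- Q * d + (1 - d) * 0.5` with retention `d = eta_decay + s * I`
#' (`d = 1` leaves values unchanged).  Chosen entries are untouched.
#'
#' @param state a Q state.
#' @param chosen list with `s1_action`, `s2_state`, `s2_action`.
#' @param params named list with `eta_decay` (and optional shift).
#' @param I context indicator.
#' @export
decay_unchosen <- function(state, chosen, params, I = 0) {
  d <- .eff(params, "eta_decay", I)
  if (d < 0 || d > 1) stop("effective decay rate must lie in [0, 1]")
  relax <- function(q) q * d + (1 - d) * 0.5
  other1 <- 3 - chosen$s1_action
  state$q_mf_s1[other1] <- relax(state$q_mf_s1[other1])
  for (s in 1:2) for (a in 1:2)
    if (!(s == chosen$s2_state && a == chosen$s2_action))
      state$q_mf_s2[s, a] <- relax(state$q_mf_s2[s, a])
  state
}

#' Stage-1 softmax choice probabilities
#'
#' Softmax over `beta_mb * Q_MB + beta_mf * Q_MF_S1 + rho * rep(a)` with
#' context-effective weights; `rep(a) = 1` for the previously chosen
#' stage-1 action.
#'
#' @param state a Q state.
#' @param params named list with `beta_mb`, `beta_mf`, `rho` (and shifts).
#' @param I context indicator.
#' @param prev_action previous stage-1 action (`NA` for none).
#' @param p_common transition probability for the Bellman step.
#' @return length-2 probability vector.
#' @export
s1_choice_probability <- function(state, params, I = 0,
                                  prev_action = state$last_s1_action,
                                  p_common = 0.7) {
  qmb <- mb_values(state, p_common)
  rep_a <- as.numeric(!is.na(prev_action) & seq_len(2) == prev_action)
  u <- .eff(params, "beta_mb", I) * qmb +
    .eff(params, "beta_mf", I) * state$q_mf_s1 +
    .eff(params, "rho", I) * rep_a
  e <- exp(u - max(u))
  e / sum(e)
}

#' Stage-2 softmax choice probabilities
#'
#' @param state a Q state.
#' @param params named list with `beta2` (and shift).
#' @param I context indicator.
#' @param s2_state visited stage-2 state (1 or 2).
#' @return length-2 probability vector over the state's actions.
#' @export
s2_choice_probability <- function(state, params, I = 0, s2_state) {
  u <- .eff(params, "beta2", I) * state$q_mf_s2[s2_state, ]
  e <- exp(u - max(u))
  e / sum(e)
}

#' Trial-wise RLDDM drift rates
#'
#' Stage-1 drift: `vcoeff_mb * (Q_MB[2] - Q_MB[1]) + vcoeff_mf *
#' (Q_MF[2] - Q_MF[1]) + rho * rep(a')` where `rep(a')` is +1/-1 when the
#' previous stage-1 choice was the upper/lower stimulus (0 for none).
#' Stage-2 drift: `vcoeff_s2 * (Q_S2[2] - Q_S2[1])` of the visited state.
#' With `sigmoid = TRUE` each drift passes through the bounded transform
#' with its stage's asymptote.
#'
#' @param state a Q state.
#' @param params named list with the drift coefficients (and shifts);
#'   `vmax_s1`, `vmax_s2` required when `sigmoid = TRUE`.
#' @param I context indicator.
#' @param prev_action previous stage-1 action.
#' @param s2_state visited stage-2 state.
#' @param p_common transition probability.
#' @param sigmoid apply the sigmoid transform (the `rlddm_s` variant).
#' @return named vector `c(drift_s1, drift_s2)`.
#' @export
rlddm_drifts <- function(state, params, I = 0,
                         prev_action = state$last_s1_action, s2_state,
                         p_common = 0.7, sigmoid = FALSE) {
  qmb <- mb_values(state, p_common)
  rep_a <- if (is.na(prev_action)) 0 else if (prev_action == 2) 1 else -1
  v1 <- .eff(params, "vcoeff_mb", I) * (qmb[2] - qmb[1]) +
    .eff(params, "vcoeff_mf", I) * (state$q_mf_s1[2] - state$q_mf_s1[1]) +
    .eff(params, "rho", I) * rep_a
  v2 <- .eff(params, "vcoeff_s2", I) *
    (state$q_mf_s2[s2_state, 2] - state$q_mf_s2[s2_state, 1])
  if (sigmoid) {
    v1 <- drift_sigmoid(v1, .eff(params, "vmax_s1", I))
    v2 <- drift_sigmoid(v2, .eff(params, "vmax_s2", I))
  }
  c(drift_s1 = v1, drift_s2 = v2)
}

#' Preprocess two-step response times
#'
#' Per participant and stage, flags the fastest and slowest `trim` fraction
#' of RTs (per-tail counts rounded down) and all RTs below `floor_s`
#' (default 150 ms) for exclusion from the likelihood.  Trials are kept in
#' the table — learning continues across excluded trials — with logical
#' `include_s1` / `include_s2` columns recording admissibility.
#'
#' @param trials data.frame with `subject`, `rt_s1`, `rt_s2` (positive
#'   seconds).
#' @param trim per-tail trim fraction (default 0.025).
#' @param floor_s lower admissibility bound in seconds (default 0.150).
#' @return the trials with `include_s1`/`include_s2` columns added.
#' @export
preprocess_twostep_rts <- function(trials, trim = 0.025, floor_s = 0.150) {
  if (nrow(trials) == 0) stop("empty trial data")
  stopifnot(all(c("subject", "rt_s1", "rt_s2") %in% names(trials)))
  flag <- function(rt, idx) {
    keep <- rep(TRUE, length(idx))
    k <- floor(length(idx) * trim)
    if (k > 0) {
      ord <- order(rt[idx])
      keep[ord[seq_len(k)]] <- FALSE
      keep[ord[seq(length(idx) - k + 1L, length(idx))]] <- FALSE
    }
    keep & rt[idx] >= floor_s
  }
  trials$include_s1 <- TRUE
  trials$include_s2 <- TRUE
  for (idx in split(seq_len(nrow(trials)), trials$subject)) {
    trials$include_s1[idx] <- flag(trials$rt_s1, idx)
    trials$include_s2[idx] <- flag(trials$rt_s2, idx)
  }
  trials
}

#' Pointwise log-likelihood of a two-step model
#'
#' Sequential evaluation over the trial table (per subject session, in trial
#' order): per trial the stage-1 and stage-2 choice probabilities/densities
#' are evaluated, then the model-free update and the decay of unchosen
#' values are applied.  RLDDM variants evaluate the Wiener density per stage
#' with the starting point fixed at 0.5 and stage-specific boundary
#' separation and non-decision time; stimulus 2 maps to the upper boundary.
#'
#' @param model `"softmax_hybrid"`, `"rlddm_lin"`, `"rlddm_s"` or
#'   `"rlddm_null"`.
#' @param params named list/vector of parameters (missing shifts default 0).
#' @param trials canonical two-step trial table (one subject, or pooled with
#'   a `subject` column handled by the caller); RLDDM variants expect
#'   [preprocess_twostep_rts()] flags, which default to all-included.
#' @param p_common transition probability.
#' @return per-trial log-likelihood vector (stage contributions summed).
#' @export
twostep_loglik <- function(model, params, trials, p_common = 0.7) {
  info <- model_info(model)
  if (info$task != "twostep") stop("'", model, "' is not a two-step model")
  theta <- .theta_vector(params, info)
  d <- .twostep_columns(trials)
  .loglik_twostep_cpp(info$id, theta, d$s1, d$s2state, d$a2, d$r, d$I,
                      d$rt1, d$rt2, d$include1, d$include2, d$session,
                      p_common)
}

## canonical column extraction shared by likelihood / fitting code
.twostep_columns <- function(trials) {
  stopifnot(all(c("s1_action", "s2_state", "s2_action", "reward",
                  "context") %in% names(trials)))
  n <- nrow(trials)
  grab <- function(col, default) {
    if (col %in% names(trials)) trials[[col]] else rep(default, n)
  }
  r <- as.numeric(trials$reward)
  if (any(r > 1)) r <- r / 100   # points -> [0, 1]
  list(s1 = as.integer(trials$s1_action),
       s2state = as.integer(trials$s2_state),
       a2 = as.integer(trials$s2_action),
       r = r,
       I = as.integer(trials$context),
       rt1 = .signed(grab("rt_s1", NA_real_), trials$s1_action),
       rt2 = .signed(grab("rt_s2", NA_real_), trials$s2_action),
       include1 = as.integer(grab("include_s1", TRUE)),
       include2 = as.integer(grab("include_s2", TRUE)),
       session = as.integer(grab("session", 1L)))
}

## upper boundary = stimulus 2 (canonical ordering, recorded in metadata)
.signed <- function(rt, action) {
  as.numeric(ifelse(action == 2, abs(rt), -abs(rt)))
}
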