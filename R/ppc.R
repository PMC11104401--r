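## Posterior predictive checks and model-agnostic analyses.

#' Posterior predictive check for the discounting task
#'
#' Bins each participant's trials, separately per context, into five
#' equal-count decision-conflict bins by the absolute subjective-value
#' difference (computed from the participant's median posterior log
#' discount rate, context-shifted) and compares observed mean absolute RTs
#' per bin against the mean over `n_sims` datasets simulated from the
#' posterior.
#'
#' @param fit a converged discounting `ctxfit` (DDM variant).
#' @param trials trial table (defaults to the fitted data).
#' @param n_sims simulated datasets (0 gives an observed-only report).
#' @param seed integer seed.
#' @param k_log optional per-subject named vector overriding the median
#'   posterior log discount rates (required for the value-free `ddm0`,
#'   which defines no discount rate of its own).
#' @return a `ctx_ppc` object: per-bin table and the per-context aggregate.
#' @export
ppc_discounting <- function(fit, trials = fit$data, n_sims = 100, seed = 1,
                            k_log = NULL) {
  stopifnot(inherits(fit, "ctxfit"), fit$task == "discounting")
  has_k <- "k_log" %in% fit$par_names
  if (is.null(k_log)) {
    if (!has_k)
      stop("model '", fit$model, "' has no discount rate; supply k_log ",
           "(e.g. median posteriors from a ddm_s fit)")
    km <- apply(subject_draws(fit, "k_log"), 2, stats::median)
    ks <- apply(subject_draws(fit, "s_k"), 2, stats::median)
  } else {
    km <- k_log[as.character(fit$subjects)]
    ks <- rep(0, length(km))
  }
  names(km) <- names(ks) <- as.character(fit$subjects)

  conflict <- abs(subjective_value(trials$ll_amount, trials$delay,
                                   km[as.character(trials$subject)],
                                   ks[as.character(trials$subject)],
                                   trials$context) - 20)
  bin <- .conflict_bins(conflict, trials$subject, trials$context)

  sims <- NULL
  if (n_sims > 0) {
    set.seed(seed)
    kept <- nrow(fit$chains[[1]]$mu)
    sim_rt <- matrix(NA_real_, n_sims, nrow(trials))
    for (i in seq_len(n_sims)) {
      ch <- fit$chains[[sample.int(length(fit$chains), 1)]]
      it <- sample.int(kept, 1)
      sim <- .simulate_from_draw(fit, ch$subject[it, , , drop = FALSE])
      sim_rt[i, ] <- abs(sim$rt)
    }
    sims <- colMeans(sim_rt, na.rm = TRUE)
  }

  key <- interaction(trials$subject, trials$context, bin, drop = TRUE)
  tab <- data.frame(
    subject = tapply(trials$subject, key, `[`, 1),
    context = tapply(trials$context, key, `[`, 1),
    bin = tapply(bin, key, `[`, 1),
    n = as.vector(table(key)),
    conflict_mean = tapply(conflict, key, mean),
    rt_obs = tapply(abs(trials$rt), key, mean),
    rt_sim = if (is.null(sims)) NA_real_ else tapply(sims, key, mean))
  rownames(tab) <- NULL
  agg <- stats::aggregate(cbind(rt_obs, rt_sim) ~ bin + context, tab, mean,
                          na.action = stats::na.pass)
  structure(list(task = "discounting", bins = tab, aggregate = agg,
                 n_sims = n_sims), class = "ctx_ppc")
}

## per subject x context equal-count quintile bins; bins partition trials
.conflict_bins <- function(conflict, subject, context, n_bins = 5) {
  bin <- integer(length(conflict))
  for (idx in split(seq_along(conflict),
                    interaction(subject, context, drop = TRUE))) {
    x <- conflict[idx]
    if (length(unique(x)) < n_bins)
      stop("fewer than ", n_bins, " distinct conflict values in a ",
           "subject-context cell; binning is degenerate")
    q <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1))
    b <- findInterval(x, unique(q), rightmost.closed = TRUE)
    bin[idx] <- pmin(pmax(b, 1L), n_bins)
  }
  bin
}

#' Posterior predictive check for the two-step task
#'
#' Observed versus simulated stage-2 RTs and optimal-choice proportions
#' (choosing the currently better-rewarded stage-2 option) across bins of
#' the absolute stage-2 reward difference.
#'
#' @param fit a two-step `ctxfit` (RLDDM for RT panels; softmax gives
#'   choices only).
#' @param trials trial table with `reward_s2_a1`/`reward_s2_a2` columns.
#' @param n_sims simulated datasets (default 200; 0 = observed only).
#' @param seed integer seed.
#' @return a `ctx_ppc` object.
#' @export
ppc_twostep <- function(fit, trials = fit$data, n_sims = 200, seed = 1) {
  stopifnot(inherits(fit, "ctxfit"), fit$task == "twostep")
  if (!all(c("reward_s2_a1", "reward_s2_a2") %in% names(trials)))
    stop("need both stage-2 option rewards (reward_s2_a1, reward_s2_a2)")
  rdiff <- abs(trials$reward_s2_a1 - trials$reward_s2_a2)
  optimal <- ifelse(trials$reward_s2_a2 >= trials$reward_s2_a1, 2L, 1L)
  bin <- .conflict_bins(rdiff, trials$subject, trials$context)
  obs_opt <- as.integer(trials$s2_action == optimal)

  sim_rt <- sim_opt <- NULL
  if (n_sims > 0) {
    set.seed(seed)
    kept <- nrow(fit$chains[[1]]$mu)
    m_rt <- matrix(NA_real_, n_sims, nrow(trials))
    m_opt <- matrix(NA_real_, n_sims, nrow(trials))
    for (i in seq_len(n_sims)) {
      ch <- fit$chains[[sample.int(length(fit$chains), 1)]]
      it <- sample.int(kept, 1)
      sim <- .simulate_from_draw(fit, ch$subject[it, , , drop = FALSE])
      m_rt[i, ] <- sim$rt_s2
      m_opt[i, ] <- as.integer(sim$s2_action == optimal)
    }
    sim_rt <- colMeans(m_rt, na.rm = TRUE)
    sim_opt <- colMeans(m_opt)
  }

  key <- interaction(trials$subject, trials$context, bin, drop = TRUE)
  tab <- data.frame(
    subject = tapply(trials$subject, key, `[`, 1),
    context = tapply(trials$context, key, `[`, 1),
    bin = tapply(bin, key, `[`, 1),
    n = as.vector(table(key)),
    rdiff_mean = tapply(rdiff, key, mean),
    rt_obs = if ("rt_s2" %in% names(trials))
      tapply(trials$rt_s2, key, mean) else NA_real_,
    rt_sim = if (is.null(sim_rt)) NA_real_ else tapply(sim_rt, key, mean),
    p_optimal_obs = tapply(obs_opt, key, mean),
    p_optimal_sim = if (is.null(sim_opt)) NA_real_ else
      tapply(sim_opt, key, mean))
  rownames(tab) <- NULL
  agg <- stats::aggregate(
    cbind(rt_obs, rt_sim, p_optimal_obs, p_optimal_sim) ~ bin, tab, mean,
    na.action = stats::na.pass)
  structure(list(task = "twostep", bins = tab, aggregate = agg,
                 n_sims = n_sims), class = "ctx_ppc")
}

#' @export
print.ctx_ppc <- function(x, ...) {
  cat("Posterior predictive check (", x$task, " task, ", x$n_sims,
      " simulated datasets)\n", sep = "")
  print(round(as.data.frame(lapply(x$aggregate, function(c)
    if (is.numeric(c)) c else c)), 3))
  invisible(x)
}

#' Choice accuracy of a fitted model
#'
#' Fraction of observed choices that the model assigns predicted
#' probability > 0.5 (`"posterior-mean"` mode: subject-level posterior-mean
#' parameters, exact choice probabilities, ties counted 0.5) or that match
#' the majority simulated choice (`"posterior-predictive"` mode).
#'
#' @param fit a `ctxfit`.
#' @param trials trial table (defaults to the fitted data).
#' @param mode `"posterior-mean"` or `"posterior-predictive"`.
#' @param n_sims simulations for predictive mode.
#' @param seed integer seed (predictive mode).
#' @return data.frame with one accuracy per stage and context plus the
#'   overall per-stage values.
#' @export
choice_accuracy <- function(fit, trials = fit$data,
                            mode = c("posterior-mean",
                                     "posterior-predictive"),
                            n_sims = 100, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "ctxfit"))
  if (mode == "posterior-mean") {
    pc <- .choice_probs(fit, trials)   # list of per-stage P(chosen)
    score <- function(p) mean((p > 0.5) + 0.5 * (p == 0.5))
  } else {
    set.seed(seed)
    kept <- nrow(fit$chains[[1]]$mu)
    match1 <- match2 <- matrix(NA_real_, n_sims, nrow(trials))
    for (i in seq_len(n_sims)) {
      ch <- fit$chains[[sample.int(length(fit$chains), 1)]]
      it <- sample.int(kept, 1)
      sim <- .simulate_from_draw(fit, ch$subject[it, , , drop = FALSE])
      if (fit$task == "discounting") {
        match1[i, ] <- as.integer(sim$choice == trials$choice)
      } else {
        match1[i, ] <- as.integer(sim$s1_action == trials$s1_action)
        match2[i, ] <- as.integer(sim$s2_action == trials$s2_action)
      }
    }
    maj <- function(m) {
      p <- colMeans(m)
      mean((p > 0.5) + 0.5 * (p == 0.5))
    }
  }
  stages <- if (fit$task == "discounting") "choice" else c("s1", "s2")
  rows <- list()
  for (st in seq_along(stages)) {
    p_st <- if (mode == "posterior-mean") pc[[st]] else NULL
    for (cx in c(0, 1, NA)) {
      sel <- if (is.na(cx)) rep(TRUE, nrow(trials)) else
        trials$context == cx
      if (!any(sel)) next
      accuracy <- if (mode == "posterior-mean") score(p_st[sel]) else
        maj((if (st == 1) match1 else match2)[, sel, drop = FALSE])
      rows[[length(rows) + 1L]] <-
        data.frame(stage = stages[st],
                   context = if (is.na(cx)) "all" else as.character(cx),
                   accuracy = accuracy)
    }
  }
  do.call(rbind, rows)
}

## exact per-trial probability of the observed choice under subject-level
## posterior-mean parameters
.choice_probs <- function(fit, trials) {
  pm <- vapply(fit$par_names, function(p) colMeans(subject_draws(fit, p)),
               numeric(length(fit$subjects)))
  if (length(fit$subjects) == 1) pm <- matrix(pm, 1,
                                              dimnames = list(NULL,
                                                              fit$par_names))
  info <- model_info(fit$model)
  if (fit$task == "discounting") {
    p_ll <- numeric(nrow(trials))
    for (si in seq_along(fit$subjects)) {
      idx <- which(trials$subject == fit$subjects[si])
      th <- as.list(pm[si, ])
      I <- trials$context[idx]
      if (fit$model == "softmax") {
        sv <- subjective_value(trials$ll_amount[idx], trials$delay[idx],
                               th$k_log, th$s_k %||% 0, I)
        p_ll[idx] <- softmax_ll_probability(sv, th$beta, th$s_beta %||% 0,
                                            I)
      } else {
        drift <- switch(fit$model,
          ddm0 = (th$v %||% 0) + (th$s_v %||% 0) * I,
          ddm_lin = drift_linear(
            subjective_value(trials$ll_amount[idx], trials$delay[idx],
                             th$k_log, th$s_k %||% 0, I),
            th$v_coeff, th$s_v_coeff %||% 0, I),
          ddm_s = drift_sigmoid(drift_linear(
            subjective_value(trials$ll_amount[idx], trials$delay[idx],
                             th$k_log, th$s_k %||% 0, I),
            th$v_coeff, th$s_v_coeff %||% 0, I),
            th$v_max, th$s_v_max %||% 0, I))
        a <- th$alpha + (th$s_alpha %||% 0) * I
        z <- th$z + (th$s_z %||% 0) * I
        p_ll[idx] <- wiener_upper_prob(a, z, drift)
      }
    }
    p_chosen <- ifelse(trials$choice == 1, p_ll, 1 - p_ll)
    return(list(p_chosen))
  }
  ## two-step: sequential replay with the R-level reference operations
  p1 <- p2 <- numeric(nrow(trials))
  is_ddm <- fit$model != "softmax_hybrid"
  sess <- trials$session %||% rep(1L, nrow(trials))
  for (si in seq_along(fit$subjects)) {
    idx <- which(trials$subject == fit$subjects[si])
    th <- as.list(pm[si, ])
    state <- qstate_init()
    last_session <- NA
    for (t in idx) {
      if (!identical(sess[t], last_session)) {
        state <- qstate_init()
        last_session <- sess[t]
      }
      I <- trials$context[t]
      tr <- list(s1_action = trials$s1_action[t],
                 s2_state = trials$s2_state[t],
                 s2_action = trials$s2_action[t],
                 reward = trials$reward[t] /
                   (if (max(trials$reward) > 1) 100 else 1))
      if (!is_ddm) {
        pp1 <- s1_choice_probability(state, th, I, p_common = fit$p_common)
        pp2 <- s2_choice_probability(state, th, I, tr$s2_state)
        p1[t] <- pp1[tr$s1_action]; p2[t] <- pp2[tr$s2_action]
      } else if (fit$model == "rlddm_null") {
        v1 <- th$v_s1 + (th$s_v_s1 %||% 0) * I
        v2 <- th$v_s2 + (th$s_v_s2 %||% 0) * I
        pu1 <- wiener_upper_prob(th$alpha_s1 + (th$s_alpha_s1 %||% 0) * I,
                                 0.5, v1)
        pu2 <- wiener_upper_prob(th$alpha_s2 + (th$s_alpha_s2 %||% 0) * I,
                                 0.5, v2)
        p1[t] <- if (tr$s1_action == 2) pu1 else 1 - pu1
        p2[t] <- if (tr$s2_action == 2) pu2 else 1 - pu2
      } else {
        v <- rlddm_drifts(state, th, I, s2_state = tr$s2_state,
                          p_common = fit$p_common,
                          sigmoid = fit$model == "rlddm_s")
        pu1 <- wiener_upper_prob(th$alpha_s1 + (th$s_alpha_s1 %||% 0) * I,
                                 0.5, v[["drift_s1"]])
        pu2 <- wiener_upper_prob(th$alpha_s2 + (th$s_alpha_s2 %||% 0) * I,
                                 0.5, v[["drift_s2"]])
        p1[t] <- if (tr$s1_action == 2) pu1 else 1 - pu1
        p2[t] <- if (tr$s2_action == 2) pu2 else 1 - pu2
      }
      if (fit$model != "rlddm_null") {
        state <- mf_update(state, tr, th, I)
        state <- decay_unchosen(state, tr, th, I)
      }
    }
  }
  list(p1, p2)
}

#' Stay-probability analysis of two-step behavior
#'
#' The classic model-agnostic signature: the probability of repeating the
#' previous stage-1 choice as a function of the previous trial's (centered)
#' reward and transition type, with subject as random effect.  A model-free
#' learner shows a reward main effect; a model-based learner a reward x
#' transition interaction.
#'
#' @param trials two-step trial table (>= 2 trials per subject).
#' @param context_interaction include context interaction terms.
#' @return list with `table` (raw stay proportions by median-split reward x
#'   transition), `model` (the fitted `glmer`) and `coefficients`.
#' @export
stay_probability_analysis <- function(trials, context_interaction = FALSE) {
  d <- .stay_frame(trials)
  if (nrow(d) < 2) stop("insufficient data for stay analysis")
  ## effect coding (+0.5 common / -0.5 rare): the reward main effect is the
  ## transition-averaged slope (model-free signature) and the interaction
  ## the common-vs-rare slope difference (model-based signature)
  form <- if (context_interaction)
    stay ~ prev_reward_c * prev_transition_e * context + (1 | subject)
  else stay ~ prev_reward_c * prev_transition_e + (1 | subject)
  if (stats::var(d$stay) == 0) {
    # a degenerate (always-stay / always-switch) response admits no
    # regression; report the raw proportions only
    fit <- NULL
    coefs <- data.frame(term = character(), estimate = numeric(),
                        se = numeric(), z = numeric(), p = numeric())
  } else {
    fit <- lme4::glmer(form, data = d, family = stats::binomial,
                       nAGQ = 0L)
    co <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(co), estimate = co[, 1],
                        se = co[, 2], z = co[, 3], p = co[, 4],
                        row.names = NULL)
  }
  hi <- d$prev_reward_c > stats::median(d$prev_reward_c)
  tab <- stats::aggregate(
    stay ~ reward_level + prev_transition,
    data.frame(d, reward_level = ifelse(hi, "high", "low")), mean)
  list(table = tab, model = fit, coefficients = coefs)
}

.stay_frame <- function(trials) {
  parts <- split(seq_len(nrow(trials)),
                 interaction(trials$subject,
                             trials$session %||% rep(1, nrow(trials)),
                             drop = TRUE))
  rows <- lapply(parts, function(idx) {
    if (length(idx) < 2) return(NULL)
    cur <- idx[-1]; prev <- idx[-length(idx)]
    data.frame(subject = trials$subject[cur],
               context = trials$context[cur],
               stay = as.integer(trials$s1_action[cur] ==
                                   trials$s1_action[prev]),
               prev_reward = trials$reward[prev],
               prev_transition = factor(trials$transition[prev],
                                        levels = c("common", "rare")))
  })
  d <- do.call(rbind, rows)
  d$prev_reward_c <- (d$prev_reward - mean(d$prev_reward)) /
    max(stats::sd(d$prev_reward), 1e-9)
  d$prev_transition_e <- ifelse(d$prev_transition == "common", 0.5, -0.5)
  d
}

#' Model-agnostic context mixed models
#'
#' For discounting data: logistic mixed regression of larger-later choice
#' on context (fixed) with subject as random effect.  For two-step data:
#' linear mixed regression of stage-2 RTs on transition type and context.
#' Standard mixed-model machinery (lme4); p-values for the linear model use
#' the normal approximation on t.
#'
#' @param trials canonical trial table of either task.
#' @return list with `model` and a `coefficients` data.frame.
#' @export
context_glmms <- function(trials) {
  if (length(unique(trials$context)) < 2)
    stop("both contexts must be present")
  if ("choice" %in% names(trials) && "ll_amount" %in% names(trials)) {
    fit <- lme4::glmer(choice ~ context + (1 | subject), trials,
                       family = stats::binomial, nAGQ = 0L)
    co <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(co), estimate = co[, 1],
                        se = co[, 2], z = co[, 3], p = co[, 4],
                        row.names = NULL)
  } else if ("rt_s2" %in% names(trials)) {
    d <- trials
    d$transition <- factor(d$transition, levels = c("common", "rare"))
    fit <- lme4::lmer(rt_s2 ~ transition + context + (1 | subject), d)
    co <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(co), estimate = co[, 1],
                        se = co[, 2], z = co[, 1] / co[, 2],
                        p = 2 * stats::pnorm(-abs(co[, 1] / co[, 2])),
                        row.names = NULL)
  } else stop("unrecognized trial table")
  list(model = fit, coefficients = coefs)
}
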