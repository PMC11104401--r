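# Shared fixture builders: small simulated cohorts under fixed seeds.
# All fixtures are generated in code at test time.

quiet_discounting_cohort <- function(n_subjects, model, seed,
                                     group_means = list(),
                                     group_sds = list()) {
  spec <- cohort_spec(n_subjects, model, group_means, group_sds, seed = seed)
  suppressMessages(simulate_discounting_cohort(spec))
}

quiet_twostep_cohort <- function(n_subjects, model, seed,
                                 group_means = list(), group_sds = list()) {
  spec <- cohort_spec(n_subjects, model, group_means, group_sds, seed = seed)
  simulate_twostep_cohort(spec)
}

# fast MCMC settings for smoke-level fits
smoke_mcmc <- function(burnin = 300, iter = 400, chains = 2, ...) {
  mcmc_control(chains = chains, burnin = burnin, iter = iter, thin = 2,
               max_extend = 0, n_loglik_draws = 50, ...)
}

# replay a two-step trial table through the R-level reference operations,
# returning per-trial log-likelihoods (softmax rule); used as the
# independent oracle for the compiled sequential likelihood
reference_hybrid_loglik <- function(params, trials, p_common = 0.7) {
  out <- numeric(nrow(trials))
  sess <- if ("session" %in% names(trials)) trials$session else
    rep(1L, nrow(trials))
  state <- qstate_init()
  last <- NA
  for (t in seq_len(nrow(trials))) {
    if (!identical(sess[t], last)) {
      state <- qstate_init()
      last <- sess[t]
    }
    I <- trials$context[t]
    tr <- list(s1_action = trials$s1_action[t],
               s2_state = trials$s2_state[t],
               s2_action = trials$s2_action[t],
               reward = trials$reward[t] / 100)
    p1 <- s1_choice_probability(state, params, I, p_common = p_common)
    p2 <- s2_choice_probability(state, params, I, tr$s2_state)
    out[t] <- log(p1[tr$s1_action]) + log(p2[tr$s2_action])
    state <- mf_update(state, tr, params, I)
    state <- decay_unchosen(state, tr, params, I)
  }
  out
}
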