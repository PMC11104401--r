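# Posterior predictive checks, choice accuracy and the model-agnostic
# mixed models.

test_that("conflict binning partitions each subject-context cell into quintiles", {
  dat <- quiet_discounting_cohort(3, "ddm_s", seed = 201)
  pp <- preprocess_discounting_rts(dat)
  fit <- suppressWarnings(
    fit_hierarchical("ddm_s", pp, mcmc = smoke_mcmc(150, 200), seed = 11))
  rep <- ppc_discounting(fit, n_sims = 5, seed = 3)
  expect_s3_class(rep, "ctx_ppc")
  counts <- aggregate(n ~ subject + context, rep$bins, sum)
  obs <- as.data.frame(table(subject = pp$subject, context = pp$context))
  expect_equal(sum(counts$n), nrow(pp))      # bins partition the trials
  expect_true(all(rep$bins$bin %in% 1:5))
  expect_true(all(is.finite(rep$bins$rt_sim)))
  # n_sims = 0: observed-only report
  rep0 <- ppc_discounting(fit, n_sims = 0)
  expect_true(all(is.na(rep0$bins$rt_sim)))
})

test_that("degenerate conflict distributions are rejected", {
  dat <- quiet_discounting_cohort(2, "ddm_s", seed = 202)
  pp <- preprocess_discounting_rts(dat)
  pp$delay <- 0           # constant (zero) conflict spread across trials
  pp$ll_amount <- 30
  fit <- suppressWarnings(
    fit_hierarchical("ddm_s", preprocess_discounting_rts(
      quiet_discounting_cohort(2, "ddm_s", seed = 202)),
      mcmc = smoke_mcmc(80, 100), seed = 12))
  expect_error(ppc_discounting(fit, trials = pp, n_sims = 0),
               "degenerate")
})

test_that("accuracy is near chance for indifferent agents and high for determined ones", {
  # uniform-choice agent
  spec <- cohort_spec(4, "softmax",
                      group_means = list(beta = 0, s_beta = 0, s_k = 0),
                      group_sds = list(beta = 0, s_beta = 0, s_k = 0),
                      seed = 40)
  dat <- suppressMessages(simulate_discounting_cohort(spec))
  fit <- suppressWarnings(
    fit_hierarchical("softmax", dat, mcmc = smoke_mcmc(150, 200),
                     seed = 13))
  acc <- choice_accuracy(fit)
  expect_equal(acc$accuracy[acc$context == "all"], 0.5, tolerance = 0.06)
  # near-deterministic agent
  spec2 <- cohort_spec(4, "softmax",
                       group_means = list(beta = 1.9, s_beta = 0, s_k = 0,
                                          k_log = -5),
                       group_sds = list(beta = 0.05, s_beta = 0, s_k = 0,
                                        k_log = 0.3),
                       seed = 41)
  dat2 <- suppressMessages(simulate_discounting_cohort(spec2))
  fit2 <- suppressWarnings(
    fit_hierarchical("softmax", dat2, mcmc = smoke_mcmc(200, 250),
                     seed = 14))
  acc2 <- choice_accuracy(fit2)
  expect_gt(acc2$accuracy[acc2$context == "all"], 0.9)
  # predictive mode agrees with posterior-mean mode directionally
  accp <- choice_accuracy(fit2, mode = "posterior-predictive", n_sims = 21)
  expect_gt(accp$accuracy[accp$context == "all"], 0.85)
})

test_that("an always-repeating agent has stay probability one", {
  dat <- quiet_twostep_cohort(2, "softmax_hybrid", seed = 203)
  dat$s1_action <- 1L
  res <- suppressMessages(stay_probability_analysis(dat))
  expect_true(all(res$table$stay == 1))
})

test_that("context mixed models recover planted effects", {
  # null simulation: no context effect on choice
  dat0 <- quiet_discounting_cohort(12, "softmax",
                                   group_means = list(s_k = 0, s_beta = 0),
                                   group_sds = list(s_k = 0, s_beta = 0),
                                   seed = 204)
  g0 <- context_glmms(dat0)
  ctx0 <- g0$coefficients[g0$coefficients$term == "context", ]
  expect_gt(ctx0$p, 0.01)
  # steeper discounting in the gambling context: negative LL-choice effect
  dat1 <- quiet_discounting_cohort(12, "softmax",
                                   group_means = list(s_k = 1),
                                   group_sds = list(s_k = 0.2), seed = 205)
  g1 <- context_glmms(dat1)
  ctx1 <- g1$coefficients[g1$coefficients$term == "context", ]
  expect_lt(ctx1$estimate, 0)
  expect_lt(ctx1$p, 0.001)
  # planted rare-transition slowing in stage-2 RTs
  dat2 <- quiet_twostep_cohort(8, "softmax_hybrid", seed = 206)
  dat2$rt_s2 <- 0.5 + 0.15 * (dat2$transition == "rare") +
    rnorm(nrow(dat2), 0, 0.1)
  g2 <- context_glmms(dat2[, setdiff(names(dat2), c("choice",
                                                    "ll_amount"))])
  tr <- g2$coefficients[g2$coefficients$term == "transitionrare", ]
  expect_gt(tr$estimate, 0.1)
  expect_lt(tr$p, 1e-6)
  expect_error(context_glmms(dat0[dat0$context == 0, ]), "contexts")
})

test_that("two-step PPC reproduces optimal-choice and RT gradients", {
  dat <- quiet_twostep_cohort(4, "softmax_hybrid", seed = 207)
  fit <- suppressWarnings(
    fit_hierarchical("softmax_hybrid", dat, mcmc = smoke_mcmc(150, 200),
                     seed = 15))
  rep <- ppc_twostep(fit, n_sims = 10, seed = 4)
  agg <- rep$aggregate
  # the chance of picking the better stage-2 option grows with the
  # reward separation, in both observed and simulated data
  expect_gt(agg$p_optimal_obs[5], agg$p_optimal_obs[1])
  expect_gt(agg$p_optimal_sim[5], agg$p_optimal_sim[1])
  expect_lt(mean(abs(agg$p_optimal_sim - agg$p_optimal_obs)), 0.1)
})
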