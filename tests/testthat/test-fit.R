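# Hierarchical fitting: recovery smoke tests, covariate extension,
# input validation.  Deeper recovery/calibration runs live in
# test-acceptance.R.

test_that("softmax group means are recovered on a small cohort", {
  dat <- quiet_discounting_cohort(10, "softmax", seed = 101)
  tp <- attr(dat, "subject_params")
  fit <- suppressWarnings(
    fit_hierarchical("softmax", dat, mcmc = smoke_mcmc(400, 600),
                     seed = 5))
  est <- coef(fit)
  expect_lt(abs(est["k_log"] - mean(tp[, "k_log"])), 0.5)
  expect_lt(abs(est["beta"] - mean(tp[, "beta"])), 0.05)
  # subject-level discount rates track the truth
  r <- cor(tp[, "k_log"], colMeans(subject_draws(fit, "k_log")))
  expect_gt(r, 0.8)
  # fit object integrity
  expect_s3_class(fit, "ctxfit")
  expect_equal(ncol(fit$pointwise_loglik), nrow(dat))
  expect_true(all(is.finite(fit$pointwise_loglik)))
  s <- summary(fit)
  expect_true(all(c("parameter", "mean", "hdi95_low", "rhat",
                    "directional_bf") %in% names(s)))
  expect_equal(nrow(s), 4)
})

test_that("posterior predictive simulation replays the trial structure", {
  dat <- quiet_discounting_cohort(4, "softmax", seed = 102)
  fit <- suppressWarnings(
    fit_hierarchical("softmax", dat, mcmc = smoke_mcmc(100, 200),
                     seed = 6))
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_length(sims, 3)
  expect_equal(dim(sims[[1]]), dim(dat))
  expect_true(all(sims[[1]]$choice %in% 0:1))
  # amounts/delays/contexts are replayed unchanged
  expect_equal(sims[[2]]$ll_amount, dat$ll_amount)
  expect_equal(sims[[2]]$context, dat$context)
})

test_that("covariate extension recovers a planted slope and fails a permuted one", {
  set.seed(7)
  n <- 24
  score <- rnorm(n)
  s_k_mean <- 0.2 + 0.5 * score
  dat <- do.call(rbind, lapply(seq_len(n), function(s) {
    spec <- cohort_spec(1, "softmax",
                        group_means = list(s_k = s_k_mean[s]),
                        group_sds = list(s_k = 0.05), seed = 300 + s)
    d <- suppressMessages(simulate_discounting_cohort(spec))
    d$subject <- s
    d
  }))
  cov <- data.frame(subject = seq_len(n), grcs = score)
  fit <- suppressWarnings(
    fit_shift_covariate_model("softmax", dat, cov,
                              mcmc = smoke_mcmc(400, 600), seed = 8))
  b <- coef(fit)
  expect_lt(abs(b[["b_grcs"]] - 0.5 * sd(score)), 0.25)
  s <- summary(fit)
  slope <- s[s$parameter == "slope_grcs", ]
  expect_gt(slope$mean, 0.1)
  expect_gt(slope$directional_bf, 3)
  # permuting the covariate rows destroys the association
  cov_perm <- cov
  cov_perm$grcs <- cov$grcs[c(13:24, 1:12)]
  fit_p <- suppressWarnings(
    fit_shift_covariate_model("softmax", dat, cov_perm,
                              mcmc = smoke_mcmc(400, 600), seed = 9))
  sp <- summary(fit_p)
  slope_p <- sp[sp$parameter == "slope_grcs", ]
  expect_lt(slope_p$hdi95_low, 0)
  expect_gt(slope_p$hdi95_high, -0.1)
  # covariate/subject mismatch is rejected
  expect_error(fit_shift_covariate_model("softmax", dat, cov[-1, ],
                                         mcmc = smoke_mcmc(50, 50)),
               "mismatch")
})

test_that("fitting validates data and model compatibility", {
  dat <- quiet_discounting_cohort(2, "ddm_s", seed = 103)
  # unpreprocessed RTs (no signed values) are rejected for DDM variants
  expect_error(fit_hierarchical("ddm_s", dat, mcmc = smoke_mcmc(10, 20)),
               "preprocess")
  expect_error(fit_hierarchical("softmax", dat[, c("subject", "context")],
                                mcmc = smoke_mcmc(10, 20)),
               "mandatory")
  expect_error(fit_hierarchical("nosuch", dat), "unknown model")
})

test_that("two identical well-mixed chains pass the R-hat gate", {
  dat <- quiet_discounting_cohort(4, "softmax", seed = 104)
  fit <- suppressWarnings(
    fit_hierarchical("softmax", dat,
                     mcmc = mcmc_control(chains = 2, burnin = 600,
                                         iter = 1500, thin = 3,
                                         max_extend = 1,
                                         n_loglik_draws = 40),
                     seed = 10))
  expect_lt(median(fit$rhat, na.rm = TRUE), 1.02)
})
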