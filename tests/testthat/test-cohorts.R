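test_that("deterministic softmax agents with valuable LL options always take them", {
  spec <- cohort_spec(2, "softmax",
                      group_means = list(k_log = -12, s_k = 0, beta = 50,
                                         s_beta = 0),
                      group_sds = list(k_log = 0.01, beta = 0.01,
                                       s_k = 0, s_beta = 0), seed = 2)
  dat <- suppressMessages(simulate_discounting_cohort(spec))
  # k ~ e^-12: SV(LL) > 20 on every trial, beta huge -> all LL choices
  expect_true(all(dat$choice == 1))
})

test_that("a positive discount-rate shift lowers LL choice in the gambling context", {
  dat <- quiet_discounting_cohort(20, "softmax",
                                  group_means = list(s_k = 0.8), seed = 6)
  p <- tapply(dat$choice, dat$context, mean)
  expect_lt(p["1"], p["0"])
})

test_that("cohort specs validate their inputs", {
  expect_error(cohort_spec(0, "softmax"))
  expect_error(cohort_spec(3, "softmax", group_sds = list(k_log = -1)))
  expect_error(cohort_spec(3, "nosuchmodel"))
})

test_that("simulated data carry generating parameters and both sessions", {
  dat <- quiet_discounting_cohort(3, "ddm_lin", seed = 4)
  expect_equal(dim(attr(dat, "subject_params")),
               c(3, length(model_info("ddm_lin")$all_pars)))
  expect_setequal(unique(dat$context), c(0, 1))
  expect_true(all(dat$rt > dat$ss_amount * 0))  # RTs positive
  # session 2 of subject 1 uses the other task version
  v <- tapply(dat$version, interaction(dat$subject, dat$session),
              unique)
  expect_setequal(unique(as.vector(v)), c(1, 2))
})

test_that("two-step cohorts respect the transition structure and walks", {
  dat <- quiet_twostep_cohort(6, "softmax_hybrid", seed = 9)
  expect_equal(mean(dat$transition == "common"), 0.7, tolerance = 0.03)
  # common transitions land in the preferred state
  common <- dat$transition == "common"
  expect_true(all(dat$s2_state[common] == dat$s1_action[common]))
  expect_true(all(dat$s2_state[!common] == 3 - dat$s1_action[!common]))
  expect_true(all(dat$reward >= 0 & dat$reward <= 100))
  # the delivered reward equals the chosen option's walk value
  chosen <- ifelse(dat$s2_action == 1, dat$reward_s2_a1, dat$reward_s2_a2)
  expect_equal(dat$reward, chosen)
})

test_that("value-blind agents choose stage-1 actions uniformly", {
  spec <- cohort_spec(4, "softmax_hybrid",
                      group_means = list(beta_mb = 0, beta_mf = 0,
                                         beta2 = 0, rho = 0, s_eta1 = 0,
                                         s_eta2 = 0, s_beta_mb = 0,
                                         s_beta_mf = 0, s_beta2 = 0,
                                         s_rho = 0),
                      group_sds = list(beta_mb = 0, beta_mf = 0, beta2 = 0,
                                       rho = 0, s_eta1 = 0, s_eta2 = 0,
                                       s_beta_mb = 0, s_beta_mf = 0,
                                       s_beta2 = 0, s_rho = 0),
                      seed = 10)
  dat <- simulate_twostep_cohort(spec)
  expect_equal(mean(dat$s1_action == 1), 0.5, tolerance = 0.03)
})

test_that("MB-only and MF-only agents leave their stay-probability signatures", {
  mb_only <- quiet_twostep_cohort(
    12, "softmax_hybrid",
    group_means = list(beta_mb = 8, beta_mf = 0, rho = 0, s_beta_mb = 0,
                       s_beta_mf = 0, s_rho = 0, s_eta1 = 0, s_eta2 = 0,
                       s_beta2 = 0),
    group_sds = list(beta_mb = 1, beta_mf = 0, rho = 0, s_beta_mb = 0,
                     s_beta_mf = 0, s_rho = 0, s_eta1 = 0, s_eta2 = 0,
                     s_beta2 = 0),
    seed = 21)
  res_mb <- stay_probability_analysis(mb_only)
  co <- res_mb$coefficients
  inter <- co[co$term == "prev_reward_c:prev_transition_e", ]
  main <- co[co$term == "prev_reward_c", ]
  # MB agent: reward x transition interaction dominates, reward main
  # effect (transition-averaged slope) near zero
  expect_gt(inter$estimate, 0)
  expect_lt(inter$p, 0.01)
  expect_lt(abs(main$estimate), abs(inter$estimate) / 2)

  mf_only <- quiet_twostep_cohort(
    12, "softmax_hybrid",
    group_means = list(beta_mb = 0, beta_mf = 8, rho = 0, s_beta_mb = 0,
                       s_beta_mf = 0, s_rho = 0, s_eta1 = 0, s_eta2 = 0,
                       s_beta2 = 0),
    group_sds = list(beta_mb = 0, beta_mf = 1, rho = 0, s_beta_mb = 0,
                     s_beta_mf = 0, s_rho = 0, s_eta1 = 0, s_eta2 = 0,
                     s_beta2 = 0),
    seed = 22)
  res_mf <- stay_probability_analysis(mf_only)
  co2 <- res_mf$coefficients
  main2 <- co2[co2$term == "prev_reward_c", ]
  expect_gt(main2$estimate, 0)
  expect_lt(main2$p, 0.01)
})

test_that("likelihood of simulated data peaks near generating parameters", {
  dat <- quiet_discounting_cohort(1, "softmax", seed = 30)
  th <- as.list(attr(dat, "subject_params")[1, ])
  ll <- function(p) sum(discounting_loglik("softmax", p, dat))
  for (par in c("k_log", "beta")) {
    up <- th; up[[par]] <- th[[par]] * 1.5
    dn <- th; dn[[par]] <- th[[par]] * 0.5
    expect_gt(ll(th), ll(up))
    expect_gt(ll(th), ll(dn))
  }
})
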