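test_that("subjective value follows the hyperbolic form", {
  expect_equal(subjective_value(55, 0, -2), 55)       # zero delay identity
  expect_equal(subjective_value(40, 30, log(0.1)), 10)
  # doubled rate in the gambling context: 40 / (1 + 0.2 * 30)
  expect_equal(subjective_value(40, 30, log(0.1), s_k = log(2), I = 1),
               40 / 7)
  expect_error(subjective_value(40, -1, -2))
  # monotone decreasing in delay and in the effective rate
  sv <- subjective_value(60, c(0, 5, 20, 100), -3)
  expect_true(all(diff(sv) < 0))
  expect_lt(subjective_value(60, 30, -2), subjective_value(60, 30, -4))
})

test_that("softmax choice rule is logistic in the value difference", {
  expect_equal(softmax_ll_probability(35, 0), 0.5)
  expect_equal(softmax_ll_probability(35, 0.4, s_beta = -0.4, I = 1), 0.5)
  expect_equal(softmax_ll_probability(20, 1.7), 0.5)
  expect_equal(softmax_ll_probability(30, 0.1), 1 / (1 + exp(-1)))
})

test_that("drift mappings match their closed forms", {
  expect_equal(drift_linear(20, 0.5), 0)
  expect_equal(drift_linear(25, 0.2), 1)
  expect_true(all(sign(drift_linear(c(15, 25), 0.3)) == c(-1, 1)))
  expect_equal(drift_sigmoid(0, 3), 0)
  expect_equal(drift_sigmoid(50, 3), 3, tolerance = 1e-12)  # asymptote
  expect_equal(drift_sigmoid(1, 3), 6 / (1 + exp(-1)) - 3)
  expect_equal(drift_sigmoid(-2, 4), -drift_sigmoid(2, 4))  # odd
  expect_error(drift_sigmoid(1, 1, s_vmax = -2, I = 1))
})

test_that("RT preprocessing trims per-tail floor counts and signs RTs", {
  mk <- function(n) data.frame(subject = 1, choice = rep(c(1, 0), n / 2),
                               rt = seq(0.3, 3, length.out = n))
  expect_equal(nrow(preprocess_discounting_rts(mk(200))), 190)
  expect_equal(nrow(preprocess_discounting_rts(mk(140))), 134)
  out <- preprocess_discounting_rts(
    data.frame(subject = 1, choice = 0, rt = seq(0.4, 1, length.out = 20)))
  expect_true(all(out$rt < 0))              # all smaller-sooner: negative
  expect_true(all(out$rt_raw > 0))
  expect_error(preprocess_discounting_rts(mk(0)))
  expect_error(preprocess_discounting_rts(
    data.frame(subject = 1, choice = 1, rt = -1)))
})

test_that("indifferent softmax gives n log(1/2) and shifts respect contexts", {
  d <- quiet_discounting_cohort(2, "softmax", seed = 3)
  ll <- discounting_loglik("softmax", list(k_log = -3, beta = 0), d)
  expect_equal(sum(ll), nrow(d) * log(0.5))
  # without shift parameters the likelihood is context-blind
  p0 <- list(k_log = -3, beta = 0.2)
  ll0 <- discounting_loglik("softmax", p0, d)
  d_flip <- d; d_flip$context <- 1 - d_flip$context
  # flipping contexts changes nothing when all shifts are zero
  expect_equal(discounting_loglik("softmax", p0, d_flip), ll0)
})

test_that("sigmoid DDM collapses to the linear DDM in the large-asymptote limit", {
  d <- quiet_discounting_cohort(1, "ddm_lin", seed = 5)
  pp <- preprocess_discounting_rts(d)
  vc <- 0.08
  base <- list(k_log = -3.5, alpha = 1.6, tau = 0.2, z = 0.45)
  ll_lin <- discounting_loglik("ddm_lin", c(base, v_coeff = vc), pp)
  V <- 1e6
  ll_sig <- discounting_loglik("ddm_s", c(base, v_coeff = 2 * vc / V,
                                          v_max = V), pp)
  expect_equal(ll_sig, ll_lin, tolerance = 1e-6)
})

test_that("predicted LL probability rises with the value difference", {
  # absorption probability under ddm_s drifts is monotone in sv - 20
  sv <- seq(5, 60, by = 5)
  drift <- drift_sigmoid(drift_linear(sv, 0.15), 1.8)
  p <- wiener_upper_prob(1.6, 0.45, drift)
  expect_true(all(diff(p) > 0))
})

test_that("likelihood prefers generating parameters over perturbed ones", {
  d <- quiet_discounting_cohort(1, "ddm_s", seed = 8)
  pp <- preprocess_discounting_rts(d)
  th <- as.list(attr(d, "subject_params")[1, ])
  ll_true <- sum(discounting_loglik("ddm_s", th, pp))
  th_bad <- th; th_bad$k_log <- th$k_log + 1
  expect_gt(ll_true, sum(discounting_loglik("ddm_s", th_bad, pp)))
  th_bad2 <- th; th_bad2$alpha <- th$alpha * 1.5
  expect_gt(ll_true, sum(discounting_loglik("ddm_s", th_bad2, pp)))
})

test_that("likelihood rejects parameters outside the support", {
  d <- quiet_discounting_cohort(1, "ddm0", seed = 9)
  pp <- preprocess_discounting_rts(d)
  ll <- discounting_loglik("ddm0", list(alpha = -1, tau = 0.2, z = 0.5,
                                        v = 0), pp)
  expect_true(all(ll == -Inf))
  expect_error(discounting_loglik("softmax_hybrid", list(), pp))
  expect_error(discounting_loglik("softmax", list(beta = 1), pp),
               "k_log")
})
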