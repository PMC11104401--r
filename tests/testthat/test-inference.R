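# WAIC, directional Bayes factors, convergence diagnostics and model
# comparison plumbing.

# independent textbook-formula WAIC: naive direct translation, no shared
# code with compute_waic
waic_reference <- function(ll) {
  lppd <- sum(log(apply(exp(ll), 2, mean)))
  p <- sum(apply(ll, 2, var))
  -2 * (lppd - p)
}

test_that("WAIC matches hand computations and the reference formula", {
  # one trial, every draw log(0.5): p_waic = 0, WAIC = -2 log 0.5
  ll <- matrix(log(0.5), nrow = 50, ncol = 1)
  w <- compute_waic(ll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * log(0.5))
  # duplicating every trial doubles WAIC
  set.seed(1)
  m <- matrix(rnorm(200, -1, 0.3), 20, 10)
  expect_equal(compute_waic(cbind(m, m))$waic, 2 * compute_waic(m)$waic)
  # agreement with the independent implementation to 1e-10
  for (i in 1:5) {
    mm <- matrix(rnorm(30 * 17, -2, 0.5), 30, 17)
    expect_equal(compute_waic(mm)$waic, waic_reference(mm),
                 tolerance = 1e-10)
  }
  expect_error(compute_waic(matrix(c(1, -Inf), 1)))
})

test_that("directional BF matches the normal-CDF oracle and its properties", {
  set.seed(2)
  x <- rnorm(50000, 1, 1)
  bf <- directional_bf(x)
  expect_equal(bf$value, pnorm(1) / pnorm(-1), tolerance = 0.08)
  expect_equal(bf$band, "moderate")
  # symmetric draws give BF near 1
  y <- rnorm(50000)
  expect_equal(directional_bf(y)$value, 1, tolerance = 0.1)
  # reciprocal property
  expect_equal(directional_bf(-x)$value, 1 / bf$value, tolerance = 0.02)
  # invariance to permutation / chain concatenation order
  expect_equal(directional_bf(rev(x))$value, bf$value)
  # one-sided draws are capped and flagged
  capped <- suppressWarnings(directional_bf(abs(rnorm(500)) + 1))
  expect_true(capped$capped)
  expect_true(is.infinite(capped$value))
})

test_that("evidence bands follow the declared thresholds", {
  set.seed(3)
  mk <- function(target) {
    # draws with the requested positive-mass ratio
    n <- 1e5; p <- target / (1 + target)
    c(abs(rnorm(round(n * p))) + 0.5, -abs(rnorm(n - round(n * p))) - 0.5)
  }
  expect_equal(directional_bf(mk(2))$band, "anecdotal")
  expect_equal(directional_bf(mk(5))$band, "moderate")
  expect_equal(directional_bf(mk(15))$band, "strong")
  expect_equal(directional_bf(mk(50))$band, "very strong")
  expect_equal(directional_bf(mk(300))$band, "extreme")
  expect_equal(directional_bf(mk(1 / 15))$band, "strong")  # reciprocal
})

test_that("split R-hat is near 1 for well-mixed chains and large for split ones", {
  set.seed(4)
  good <- cbind(rnorm(2000), rnorm(2000))
  expect_lt(split_rhat(good), 1.01)
  bad <- cbind(rnorm(2000, 0), rnorm(2000, 3))
  expect_gt(split_rhat(bad), 1.5)
  # within-chain drift also flagged
  drift <- matrix(c(rnorm(1000, 0), rnorm(1000, 4)), ncol = 1)
  expect_gt(split_rhat(drift), 1.5)
  expect_equal(split_rhat(matrix(1, 100, 2)), 1)
})

test_that("model comparison enforces identical trial sets and self-difference is zero", {
  dat <- quiet_discounting_cohort(3, "softmax", seed = 15)
  fit <- suppressWarnings(fit_hierarchical("softmax", dat,
                                           mcmc = smoke_mcmc(100, 150),
                                           seed = 1))
  cmp <- compare_models(fit, fit)
  expect_equal(cmp$d_waic[2], 0)
  dat2 <- dat[-(1:3), ]
  fit2 <- suppressWarnings(fit_hierarchical("softmax", dat2,
                                            mcmc = smoke_mcmc(100, 150),
                                            seed = 1))
  expect_error(compare_models(fit, fit2), "fingerprint")
})

test_that("prior specification is validated against the model", {
  pr <- ctx_priors("softmax")
  expect_error(fit_hierarchical("ddm0", data.frame(), priors = pr),
               "mismatch")
  expect_error(.subset2(pr, "pars"), NA)  # structure accessible
  bad <- ctx_priors("softmax")
  bad$pars$s_k$dist$mean <- 1
  d <- quiet_discounting_cohort(2, "softmax", seed = 1)
  expect_error(fit_hierarchical("softmax", d, priors = bad), "centered")
})
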