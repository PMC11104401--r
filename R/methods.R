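## S3 methods for fitted objects.

## pooled group-level draws (across chains) for one parameter
.group_draws <- function(fit, par, what = "mu") {
  j <- match(par, fit$par_names)
  if (is.na(j)) stop("unknown parameter '", par, "'")
  unlist(lapply(fit$chains, function(ch) ch[[what]][, j]))
}

#' Posterior draws of a group-level mean
#'
#' @param fit a `ctxfit`.
#' @param par parameter name (e.g. `"s_k"`).
#' @return numeric vector of pooled posterior draws.
#' @export
shift_draws <- function(fit, par) .group_draws(fit, par, "mu")

#' Subject-level posterior draws
#'
#' @param fit a `ctxfit`.
#' @param par parameter name.
#' @return draws x subjects matrix.
#' @export
subject_draws <- function(fit, par) {
  j <- match(par, fit$par_names)
  if (is.na(j)) stop("unknown parameter '", par, "'")
  do.call(rbind, lapply(fit$chains, function(ch) ch$subject[, , j]))
}

#' Highest density interval
#'
#' Narrowest interval containing `prob` posterior mass.
#'
#' @param x draws.
#' @param prob mass (default 0.95).
#' @return length-2 vector.
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- max(1L, floor(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  w <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(w)
  c(x[i], x[i + k])
}

#' @export
print.ctxfit <- function(x, ...) {
  cat("Hierarchical context-shift fit: model '", x$model, "' (",
      x$task, " task)\n", sep = "")
  cat(sprintf("  %d subjects, %d trials, %d chains x %d retained draws\n",
              length(x$subjects), nrow(x$data), length(x$chains),
              nrow(x$chains[[1]]$mu)))
  cat(sprintf("  max R-hat %.3f (gate %.2f) - %s\n",
              max(x$rhat, na.rm = TRUE), x$mcmc$rhat_gate,
              if (x$converged) "converged" else "FLAGGED NON-CONVERGED"))
  if (!is.null(x$covariates))
    cat("  covariate model on", x$covariates$target, "with scores:",
        paste(attr(x$covariates$X, "score_names"), collapse = ", "), "\n")
  cat("  group-level posterior means:\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' Posterior means of the group-level parameters
#'
#' @param object a `ctxfit`.
#' @param ... unused.
#' @return named numeric vector (group means; covariate slopes appended
#'   when present).
#' @export
coef.ctxfit <- function(object, ...) {
  out <- vapply(object$par_names, function(p)
    mean(.group_draws(object, p)), 0)
  if (!is.null(object$covariates)) {
    b <- do.call(rbind, lapply(object$chains, `[[`, "b"))
    bm <- colMeans(b)
    names(bm) <- paste0("b_", colnames(b))
    out <- c(out, bm)
  }
  out
}

#' Posterior summary table
#'
#' One row per group-level parameter: posterior mean, SD, 85% and 95%
#' highest density intervals, split R-hat, and for context-shift parameters
#' the directional Bayes factor (mass above vs below zero) with its
#' evidence band.  Covariate slopes are appended when fitted.
#'
#' @param object a `ctxfit`.
#' @param ... unused.
#' @return data.frame of class `summary.ctxfit`.
#' @export
summary.ctxfit <- function(object, ...) {
  rows <- lapply(object$par_names, function(p) {
    d <- .group_draws(object, p)
    h85 <- hdi(d, 0.85); h95 <- hdi(d, 0.95)
    is_shift <- startsWith(p, "s_")
    bf <- if (is_shift) directional_bf(d) else NULL
    data.frame(parameter = p, mean = mean(d), sd = stats::sd(d),
               hdi85_low = h85[1], hdi85_high = h85[2],
               hdi95_low = h95[1], hdi95_high = h95[2],
               rhat = unname(object$rhat[paste0("mu_", p)]),
               directional_bf = if (is_shift) bf$value else NA_real_,
               evidence = if (is_shift) bf$band else NA_character_)
  })
  if (!is.null(object$covariates)) {
    b <- do.call(rbind, lapply(object$chains, `[[`, "b"))
    for (i in seq_len(ncol(b))[-1]) {
      d <- b[, i]
      h85 <- hdi(d, 0.85); h95 <- hdi(d, 0.95)
      bf <- directional_bf(d)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = paste0("slope_", colnames(b)[i]),
                   mean = mean(d), sd = stats::sd(d),
                   hdi85_low = h85[1], hdi85_high = h85[2],
                   hdi95_low = h95[1], hdi95_high = h95[2],
                   rhat = NA_real_, directional_bf = bf$value,
                   evidence = bf$band)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.ctxfit", "data.frame")
  out
}

#' @export
print.summary.ctxfit <- function(x, digits = 3, ...) {
  y <- x
  class(y) <- "data.frame"
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y)
  invisible(x)
}

#' Posterior predictive simulation from a fitted model
#'
#' Draws `nsim` datasets: for each, one retained posterior draw of every
#' subject's parameter vector is selected and the subject's observed trial
#' structure (options, contexts, sessions, transitions/walk rewards) is
#' replayed through the generative model.
#'
#' @param object a `ctxfit`.
#' @param nsim number of simulated datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of data.frames shaped like `object$data` with simulated
#'   `choice`/`rt` (discounting) or actions and RTs (two-step).
#' @export
simulate.ctxfit <- function(object, nsim = 1, seed = 1, ...) {
  set.seed(seed)
  kept <- nrow(object$chains[[1]]$mu)
  lapply(seq_len(nsim), function(i) {
    ch <- object$chains[[sample.int(length(object$chains), 1)]]
    it <- sample.int(kept, 1)
    .simulate_from_draw(object, ch$subject[it, , , drop = FALSE])
  })
}

.simulate_from_draw <- function(fit, th_slice) {
  info <- model_info(fit$model)
  data <- fit$data
  out <- data
  for (si in seq_along(fit$subjects)) {
    idx <- which(data$subject == fit$subjects[si])
    th <- th_slice[1, si, ]
    names(th) <- fit$par_names
    rows <- data[idx, , drop = FALSE]
    if (fit$task == "discounting") {
      sim <- .sim_discounting_trials(fit$model, th, rows)
      out$choice[idx] <- sim$choice
      if ("rt" %in% names(out)) out$rt[idx] <- sim$rt
    } else {
      sim <- .sim_twostep_trials(fit$model, th, rows, fit$p_common)
      out[idx, names(sim)] <- sim
    }
  }
  out
}

## replay one subject's discounting trials under parameters th
.sim_discounting_trials <- function(model, th, rows) {
  p <- as.list(th)
  I <- rows$context
  sv <- subjective_value(rows$ll_amount, rows$delay, p$k_log %||% 0,
                         p$s_k %||% 0, I)
  if (model == "softmax") {
    pr <- softmax_ll_probability(sv, p$beta, p$s_beta %||% 0, I)
    return(list(choice = as.integer(stats::runif(nrow(rows)) < pr),
                rt = rep(NA_real_, nrow(rows))))
  }
  drift <- switch(model,
    ddm0 = (p$v %||% 0) + (p$s_v %||% 0) * I,
    ddm_lin = drift_linear(sv, p$v_coeff, p$s_v_coeff %||% 0, I),
    ddm_s = drift_sigmoid(drift_linear(sv, p$v_coeff, p$s_v_coeff %||% 0,
                                       I),
                          p$v_max, p$s_v_max %||% 0, I))
  a <- p$alpha + (p$s_alpha %||% 0) * I
  tau <- p$tau + (p$s_tau %||% 0) * I
  z <- p$z + (p$s_z %||% 0) * I
  srt <- .wiener_sample_euler_cpp(nrow(rows), a, tau, z, drift, 1e-3, 30)
  list(choice = as.integer(srt > 0), rt = srt)
}

## replay one subject's two-step sessions (same walks) under parameters th
.sim_twostep_trials <- function(model, th, rows, p_common) {
  info <- model_info(model)
  wmat <- as.matrix(rows[, c("reward_s2_a1", "reward_s2_a2")])
  ## reconstruct a walk matrix; the unvisited state's rewards are not in
  ## the trial table, so both states replay the visited state's pair
  ## (adequate for RT/choice pattern checks)
  full <- cbind(wmat, wmat)
  roll <- .simulate_twostep_subject_cpp(
    info$id, .theta_vector(as.list(th), info), full / 100,
    as.integer(rows$context), as.integer(rows$session %||%
                                           rep(1L, nrow(rows))),
    p_common, 1e-3, 30)
  data.frame(s1_action = roll$s1,
             transition = ifelse(roll$transition == 1, "common", "rare"),
             s2_state = roll$s2_state, s2_action = roll$s2_action,
             reward = roll$reward * 100, rt_s1 = roll$rt_s1,
             rt_s2 = roll$rt_s2)
}

#' @export
logLik.ctxfit <- function(object, ...) {
  ll <- sum(log(colMeans(exp(object$pointwise_loglik))))
  structure(ll, df = NA, class = "logLik")
}

#' Plot group-level posterior densities
#'
#' Baseline parameters in the top row(s), context shifts below, with 85%
#' and 95% HDI bars, in the style of posterior panels for hierarchical
#' cognitive models.
#'
#' @param x a `ctxfit`.
#' @param pars parameters to show (default all group-level).
#' @param ... passed to `plot.density`.
#' @export
plot.ctxfit <- function(x, pars = x$par_names, ...) {
  n <- length(pars)
  mfrow <- c(ceiling(n / 4), min(4, n))
  op <- graphics::par(mfrow = mfrow, mar = c(2.5, 2, 2, 0.5))
  on.exit(graphics::par(op))
  for (p in pars) {
    d <- .group_draws(x, p)
    dens <- stats::density(d)
    plot(dens, main = p, xlab = "", ylab = "", ...)
    h95 <- hdi(d, 0.95); h85 <- hdi(d, 0.85)
    graphics::segments(h95[1], 0, h95[2], 0, lwd = 1)
    graphics::segments(h85[1], 0, h85[2], 0, lwd = 3)
    if (startsWith(p, "s_")) graphics::abline(v = 0, lty = 2)
  }
  invisible(x)
}
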