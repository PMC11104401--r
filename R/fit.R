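## Hierarchical Bayesian estimation.  Subject-level parameter vectors are
## exchangeable draws from Gaussian group-level distributions (one per
## baseline parameter and one per context shift); sampling alternates
## adaptive component-wise random-walk Metropolis sweeps over each subject's
## parameters (compiled likelihoods) with conjugate / truncated-normal Gibbs
## updates of the group-level means and precisions.  Convergence is gated on
## rank-normalized split R-hat <= the configured threshold, with automatic
## sampling extensions; a fit that still fails the gate is flagged, reported
## and returned (not discarded).

#' MCMC settings
#'
#' @param chains number of chains (default 2).
#' @param burnin adaptation/burn-in iterations per chain (discarded).
#' @param iter post-burn-in iterations per chain.
#' @param thin thinning interval (default 2).
#' @param rhat_gate convergence threshold on split R-hat (default 1.02).
#' @param max_extend maximum number of sampling extensions (each adding
#'   `iter` iterations) when the gate is not met.
#' @param adapt_batch proposal adaptation batch length during burn-in.
#' @param n_loglik_draws posterior draws at which pointwise log-likelihoods
#'   are evaluated for WAIC.
#' @return list of settings.
#' @export
mcmc_control <- function(chains = 2, burnin = 1000, iter = 2000, thin = 2,
                         rhat_gate = 1.02, max_extend = 2, adapt_batch = 25,
                         n_loglik_draws = 400) {
  stopifnot(chains >= 1, burnin >= 0, iter >= thin, thin >= 1)
  list(chains = chains, burnin = burnin, iter = iter, thin = thin,
       rhat_gate = rhat_gate, max_extend = max_extend,
       adapt_batch = adapt_batch, n_loglik_draws = n_loglik_draws)
}

#' Fit a model hierarchically
#'
#' The single fitting entry point: estimates the requested model on a
#' canonical trial table by MCMC under the package's hierarchical prior
#' scheme (uniform baseline-mean priors over plausible ranges, zero-centered
#' Gaussian shift-mean priors, Gamma priors on group precisions).  Returns a
#' `ctxfit` object with draws, convergence diagnostics and stored pointwise
#' log-likelihoods; see [summary.ctxfit()], [coef.ctxfit()],
#' [compare_models()], [directional_bf()] and the posterior predictive
#' checks.
#'
#' @param model registered model name (see [list_models()]).
#' @param data canonical trial table for the model's task.  DDM variants
#'   expect preprocessed data ([preprocess_discounting_rts()] /
#'   [preprocess_twostep_rts()]); unpreprocessed RT data are rejected.
#' @param priors a [ctx_priors()] specification.
#' @param mcmc an [mcmc_control()] list.
#' @param covariates optional per-subject data.frame (`subject` column plus
#'   numeric scores, standardized internally) modelling the group mean of
#'   `covariate_target` as a linear combination of the scores.
#' @param covariate_target shift parameter carrying the covariate model
#'   (default `"s_k"`).
#' @param p_common transition probability (two-step models).
#' @param seed integer seed; chains use derived substreams.
#' @param verbose print stage progress.
#' @return an object of class `ctxfit`.
#' @export
fit_hierarchical <- function(model, data, priors = ctx_priors(model),
                             mcmc = mcmc_control(), covariates = NULL,
                             covariate_target = "s_k", p_common = 0.7,
                             seed = 1, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  info <- model_info(model)
  .check_priors(priors, info)
  data <- .validate_fit_data(info, data)
  subjects <- sort(unique(data$subject))
  S <- length(subjects)
  sub_rows <- lapply(subjects, function(s) which(data$subject == s))
  sub_data <- lapply(sub_rows, function(idx)
    .subject_data(info$task, data[idx, , drop = FALSE], p_common))
  J <- length(info$all_pars)
  pr <- .prior_vectors(priors, info)

  X <- NULL; jstar <- NA_integer_
  if (!is.null(covariates)) {
    jstar <- match(covariate_target, info$all_pars)
    if (is.na(jstar) || !startsWith(covariate_target, "s_"))
      stop("covariate_target must be one of the model's shift parameters")
    X <- .covariate_matrix(covariates, subjects)
  }

  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    if (verbose) message("chain ", ch, "/", mcmc$chains)
    .run_chain(info, sub_data, pr, mcmc, X, jstar,
               seed = seed + 7919L * ch, n_iter = mcmc$iter,
               burnin = mcmc$burnin, state = NULL)
  })

  rhat <- .fit_rhat(chains, info)
  ext <- 0L
  while (max(rhat, na.rm = TRUE) > mcmc$rhat_gate &&
         ext < mcmc$max_extend) {
    ext <- ext + 1L
    if (verbose) message("max R-hat ", round(max(rhat, na.rm = TRUE), 3),
                         " > ", mcmc$rhat_gate, "; extending sampling (",
                         ext, "/", mcmc$max_extend, ")")
    chains <- lapply(seq_along(chains), function(ch) {
      more <- .run_chain(info, sub_data, pr, mcmc, X, jstar,
                         seed = seed + 7919L * ch + 104729L * ext,
                         n_iter = mcmc$iter, burnin = 0,
                         state = chains[[ch]]$state)
      .append_chain(chains[[ch]], more)
    })
    rhat <- .fit_rhat(chains, info)
  }
  converged <- max(rhat, na.rm = TRUE) <= mcmc$rhat_gate
  if (!converged)
    warning("fit flagged non-converged: max R-hat = ",
            round(max(rhat, na.rm = TRUE), 3), " > ", mcmc$rhat_gate,
            call. = FALSE)

  pw <- .pointwise_loglik(info, chains, sub_data, sub_rows,
                          mcmc$n_loglik_draws, nrow(data))

  structure(list(
    model = model, task = info$task, data = data, subjects = subjects,
    par_names = info$all_pars, chains = chains, rhat = rhat,
    converged = converged, pointwise_loglik = pw, priors = priors,
    mcmc = mcmc, seed = seed, p_common = p_common,
    covariates = if (is.null(X)) NULL else
      list(X = X, target = covariate_target),
    fingerprint = data_fingerprint(data),
    runtime = proc.time()[["elapsed"]] - t0), class = "ctxfit")
}

#' Fit the covariate extension of a context-shift model
#'
#' Models the group-level mean of one shift parameter (by default the
#' discount-rate shift `s_k`) as a linear combination of standardized
#' per-subject scores: `E[s_x | subject] = intercept + sum_j slope_j *
#' score_j`.  Slope posteriors are reported by [summary.ctxfit()] together
#' with their directional Bayes factors.
#'
#' @inheritParams fit_hierarchical
#' @export
fit_shift_covariate_model <- function(model, data, covariates,
                                      covariate_target = "s_k",
                                      priors = ctx_priors(model),
                                      mcmc = mcmc_control(), seed = 1, ...) {
  fit_hierarchical(model, data, priors = priors, mcmc = mcmc,
                   covariates = covariates,
                   covariate_target = covariate_target, seed = seed, ...)
}

## ------------------------------------------------------------------
## internals

.validate_fit_data <- function(info, data) {
  need <- if (info$task == "discounting")
    c("subject", "context", "ll_amount", "delay", "choice")
  else
    c("subject", "context", "s1_action", "s2_state", "s2_action", "reward")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  is_ddm <- info$model != "softmax" && info$model != "softmax_hybrid"
  if (is_ddm && info$task == "discounting") {
    if (!"rt" %in% names(data) || !any(data$rt < 0, na.rm = TRUE))
      stop("DDM variants need preprocessed signed RTs; run ",
           "preprocess_discounting_rts() first", call. = FALSE)
  }
  if (is_ddm && info$task == "twostep" &&
      !all(c("rt_s1", "rt_s2") %in% names(data)))
    stop("RLDDM variants need per-stage RTs", call. = FALSE)
  data
}

.subject_data <- function(task, trials, p_common) {
  if (task == "discounting") {
    rt <- if ("rt" %in% names(trials)) as.numeric(trials$rt) else
      rep(NA_real_, nrow(trials))
    list(A = as.numeric(trials$ll_amount), D = as.numeric(trials$delay),
         I = as.integer(trials$context), choice = as.integer(trials$choice),
         rt = rt)
  } else {
    d <- .twostep_columns(trials)
    d$p_common <- p_common
    d
  }
}

.prior_vectors <- function(priors, info) {
  J <- length(info$all_pars)
  out <- list(dist = character(J), lo = numeric(J), hi = numeric(J),
              mean = numeric(J), sd = numeric(J),
              shape = priors$precision$shape, rate = priors$precision$rate)
  for (j in seq_len(J)) {
    d <- priors$pars[[info$all_pars[j]]]$dist
    out$dist[j] <- d$dist
    if (d$dist == "uniform") { out$lo[j] <- d$lo; out$hi[j] <- d$hi }
    else { out$mean[j] <- d$mean; out$sd[j] <- d$sd }
  }
  out
}

.covariate_matrix <- function(covariates, subjects) {
  if (!"subject" %in% names(covariates))
    stop("covariates need a 'subject' column")
  idx <- match(subjects, covariates$subject)
  if (anyNA(idx))
    stop("covariate/subject mismatch: no scores for subject(s) ",
         paste(setdiff(subjects, covariates$subject), collapse = ", "))
  num <- covariates[idx, setdiff(names(covariates), "subject"),
                    drop = FALSE]
  Xs <- scale(as.matrix(num))
  Xs[is.nan(Xs)] <- 0
  X <- cbind(intercept = 1, Xs)
  attr(X, "score_names") <- colnames(num)
  X
}

## a chain: list(mu, sigma, subject, b [optional]) draw stores + final state
.run_chain <- function(info, sub_data, pr, mcmc, X, jstar, seed, n_iter,
                       burnin, state) {
  set.seed(seed %% .Machine$integer.max)
  task_id <- if (info$task == "discounting") 0L else 1L
  S <- length(sub_data)
  J <- length(info$all_pars)
  K <- J / 2

  if (is.null(state)) {
    init <- .init_state(info, sub_data, pr, X, jstar)
  } else init <- state

  theta <- init$theta; mu <- init$mu; sigma <- init$sigma
  prop_sd <- init$prop_sd; b <- init$b
  cur_ll <- rep(NA_real_, S)

  kept <- floor(n_iter / mcmc$thin)
  mu_draws <- matrix(NA_real_, kept, J,
                     dimnames = list(NULL, info$all_pars))
  sigma_draws <- mu_draws
  sub_draws <- array(NA_real_, c(kept, S, J),
                     dimnames = list(NULL, NULL, info$all_pars))
  b_draws <- if (!is.null(X)) matrix(NA_real_, kept, ncol(X),
                                     dimnames = list(NULL, colnames(X)))

  acc <- matrix(0, S, J); batch_n <- 0L; batch_no <- init$batch_no
  total <- burnin + n_iter
  k <- 0L
  for (it in seq_len(total)) {
    ## subject-level MH sweeps
    for (s in seq_len(S)) {
      mu_s <- mu
      if (!is.null(X)) mu_s[jstar] <- sum(X[s, ] * b)
      sw <- .mh_sweep_cpp(task_id, info$id, theta[s, ], sub_data[[s]],
                          mu_s, sigma, prop_sd[s, ], cur_ll[s])
      theta[s, ] <- sw$theta; cur_ll[s] <- sw$ll
      acc[s, ] <- acc[s, ] + sw$acc
    }
    batch_n <- batch_n + 1L
    if (it <= burnin && batch_n == mcmc$adapt_batch) {
      batch_no <- batch_no + 1L
      rate <- acc / batch_n
      prop_sd <- prop_sd * exp((rate - 0.44) / sqrt(batch_no))
      acc[] <- 0; batch_n <- 0L
    }

    ## group-level Gibbs
    cmean <- colMeans(theta)
    for (j in seq_len(J)) {
      if (!is.null(X) && j == jstar) next
      pv <- sigma[j]^2 / S
      if (pr$dist[j] == "uniform") {
        mu[j] <- .rtruncnorm1(cmean[j], sqrt(pv), pr$lo[j], pr$hi[j])
      } else {
        post_prec <- S / sigma[j]^2 + 1 / pr$sd[j]^2
        post_mean <- (S * cmean[j] / sigma[j]^2 +
                        pr$mean[j] / pr$sd[j]^2) / post_prec
        mu[j] <- stats::rnorm(1, post_mean, sqrt(1 / post_prec))
      }
    }
    if (!is.null(X)) {
      ## conjugate regression update for the covariate coefficients
      y <- theta[, jstar]
      prec0 <- diag(1 / 25, ncol(X))
      V <- solve(crossprod(X) / sigma[jstar]^2 + prec0)
      m <- V %*% (crossprod(X, y) / sigma[jstar]^2)
      b <- as.numeric(m + t(chol(V)) %*% stats::rnorm(ncol(X)))
      mu[jstar] <- b[1]
    }
    ## precisions
    for (j in seq_len(J)) {
      resid <- if (!is.null(X) && j == jstar) theta[, j] - X %*% b
               else theta[, j] - mu[j]
      lam <- stats::rgamma(1, pr$shape + S / 2,
                           pr$rate + sum(resid^2) / 2)
      sigma[j] <- sqrt(1 / max(lam, 1e-12))
    }

    if (it > burnin && (it - burnin) %% mcmc$thin == 0) {
      k <- k + 1L
      mu_draws[k, ] <- mu
      sigma_draws[k, ] <- sigma
      sub_draws[k, , ] <- theta
      if (!is.null(X)) b_draws[k, ] <- b
    }
  }
  list(mu = mu_draws, sigma = sigma_draws, subject = sub_draws,
       b = b_draws,
       state = list(theta = theta, mu = mu, sigma = sigma,
                    prop_sd = prop_sd, b = b, batch_no = batch_no))
}

.init_state <- function(info, sub_data, pr, X, jstar) {
  S <- length(sub_data)
  J <- length(info$all_pars)
  K <- J / 2
  task_id <- if (info$task == "discounting") 0L else 1L
  init_tab <- .par_init()

  mu <- numeric(J)
  for (j in seq_len(J)) {
    p <- info$all_pars[j]
    if (j <= K) {
      v <- init_tab[[p]]
      if (pr$dist[j] == "uniform")
        v <- min(max(v, pr$lo[j] + 0.05 * (pr$hi[j] - pr$lo[j])),
                 pr$hi[j] - 0.05 * (pr$hi[j] - pr$lo[j]))
      mu[j] <- v
    } else mu[j] <- 0
  }
  ## data-driven non-decision-time start: below each subject's fastest RT
  min_rt <- vapply(sub_data, function(d) {
    rts <- c(d$rt, d$rt1, d$rt2)
    rts <- abs(rts[is.finite(rts)])
    if (length(rts)) min(rts) else Inf
  }, 0)
  tau_idx <- which(info$pars %in% c("tau", "tau_s1", "tau_s2"))
  sigma <- rep(0.3, J)
  rate_idx <- which(info$all_pars %in%
                      c("eta1", "eta2", "eta_decay", "z",
                        paste0("s_", c("eta1", "eta2", "eta_decay", "z"))))
  sigma[rate_idx] <- 0.1

  theta <- matrix(NA_real_, S, J)
  for (s in seq_len(S)) {
    ok <- FALSE
    for (try in 1:100) {
      th <- mu + stats::rnorm(J, 0, sigma * 0.5)
      for (j in tau_idx)
        th[j] <- min(th[j], 0.7 * min_rt[s], pr$hi[j])
      th[seq_len(K)][info$pars %in% c("eta1", "eta2", "eta_decay")] <-
        pmin(pmax(th[seq_len(K)][info$pars %in%
                                   c("eta1", "eta2", "eta_decay")], 0.05),
             0.95)
      if ("z" %in% info$pars) {
        jz <- match("z", info$pars)
        th[jz] <- min(max(th[jz], 0.2), 0.8)
      }
      th[tau_idx] <- pmax(th[tau_idx], 0.01)
      th[K + seq_len(K)] <- th[K + seq_len(K)] * 0.1   # small shift starts
      ll <- .mh_sweep_cpp(task_id, info$id, th, sub_data[[s]], mu, sigma,
                          rep(1e-10, J), NA_real_)$ll
      if (is.finite(ll)) { theta[s, ] <- th; ok <- TRUE; break }
    }
    if (!ok)
      stop("could not find admissible starting values for subject ", s,
           "; check the data against the model's support", call. = FALSE)
  }
  prop_sd <- matrix(rep(pmax(sigma * 0.5, 0.02), each = S), S, J)
  b <- if (!is.null(X)) c(mu[jstar], rep(0, ncol(X) - 1))
  list(theta = theta, mu = mu, sigma = sigma, prop_sd = prop_sd, b = b,
       batch_no = 0L)
}

.rtruncnorm1 <- function(m, s, lo, hi) {
  plo <- stats::pnorm(lo, m, s); phi <- stats::pnorm(hi, m, s)
  if (phi - plo < 1e-12) return(min(max(m, lo), hi))
  stats::qnorm(stats::runif(1, plo, phi), m, s)
}

.append_chain <- function(old, more) {
  list(mu = rbind(old$mu, more$mu),
       sigma = rbind(old$sigma, more$sigma),
       subject = .abind3(old$subject, more$subject),
       b = if (!is.null(old$b)) rbind(old$b, more$b),
       state = more$state)
}

.abind3 <- function(a, b) {
  out <- array(NA_real_, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]),
               dimnames = dimnames(a))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

## rank-normalized split R-hat over all group-level and subject-level
## parameters; returns a named vector
.fit_rhat <- function(chains, info) {
  J <- length(info$all_pars)
  S <- dim(chains[[1]]$subject)[2]
  out <- c()
  for (j in seq_len(J)) {
    m <- sapply(chains, function(ch) ch$mu[, j])
    out[paste0("mu_", info$all_pars[j])] <- split_rhat(m)
    sdm <- sapply(chains, function(ch) ch$sigma[, j])
    out[paste0("sigma_", info$all_pars[j])] <- split_rhat(sdm)
  }
  sub_r <- numeric(0)
  for (j in seq_len(J)) for (s in seq_len(S)) {
    m <- sapply(chains, function(ch) ch$subject[, s, j])
    sub_r[sprintf("subj%d_%s", s, info$all_pars[j])] <- split_rhat(m)
  }
  c(out, sub_r)
}

#' Rank-normalized split R-hat
#'
#' Gelman-Rubin potential scale reduction on rank-normalized draws with
#' each chain split in half.  Values near 1 indicate mixing; the package
#' gates fits at 1.02 by default.
#'
#' @param draws iterations x chains matrix (a vector is treated as one
#'   chain).
#' @return scalar R-hat (NA for degenerate input).
#' @export
split_rhat <- function(draws) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  split <- do.call(cbind, lapply(seq_len(ncol(draws)), function(c)
    cbind(draws[seq_len(half), c],
          draws[seq(n - half + 1, n), c])))
  if (stats::sd(split) < 1e-12) return(1)
  r <- matrix(rank(split, ties.method = "average"), nrow(split))
  z <- stats::qnorm((r - 3 / 8) / (length(split) + 1 / 4))
  m <- ncol(z); nn <- nrow(z)
  cm <- colMeans(z)
  B <- nn * stats::var(cm)
  W <- mean(apply(z, 2, stats::var))
  if (W < 1e-300) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

## pointwise log-likelihood matrix (draws x trials) at a spread of retained
## posterior draws, for WAIC
.pointwise_loglik <- function(info, chains, sub_data, sub_rows, n_draws,
                              n_trials) {
  kept <- dim(chains[[1]]$subject)[1]
  per_chain <- max(1L, floor(n_draws / length(chains)))
  idx <- unique(round(seq(1, kept, length.out = per_chain)))
  total <- length(idx) * length(chains)
  out <- matrix(NA_real_, total, n_trials)
  row <- 0L
  for (ch in chains) for (i in idx) {
    row <- row + 1L
    for (s in seq_along(sub_data)) {
      th <- ch$subject[i, s, ]
      d <- sub_data[[s]]
      pw <- if (info$task == "discounting")
        .loglik_discounting_cpp(info$id, th, d$A, d$D, d$I, d$choice, d$rt)
      else
        .loglik_twostep_cpp(info$id, th, d$s1, d$s2state, d$a2, d$r, d$I,
                            d$rt1, d$rt2, d$include1, d$include2,
                            d$session, d$p_common)
      out[row, sub_rows[[s]]] <- pw
    }
  }
  out
}

#' Deterministic fingerprint of a trial table
#'
#' Used to guard model comparisons: WAIC is only meaningful across fits of
#' the identical trial set.
#'
#' @param data a data.frame.
#' @return character scalar.
#' @export
data_fingerprint <- function(data) {
  f <- tempfile()
  on.exit(unlink(f))
  num <- vapply(data, function(col) {
    if (is.numeric(col)) sum(col, na.rm = TRUE) else
      sum(nchar(as.character(col)), na.rm = TRUE)
  }, 0)
  writeLines(c(dim(data), names(data), format(num, digits = 15)), f)
  unname(tools::md5sum(f))
}
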