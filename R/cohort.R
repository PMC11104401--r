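## Simulated cohorts: subject-level parameters drawn from group-level
## normals, full generative rollouts of both tasks under every likelihood
## variant.  The default group-level values are the package's study
## conditions (documented in the methods vignette); the shift means follow
## the effect sizes the models are built to detect.

#' Cohort specification
#'
#' @param n_subjects number of simulated participants (>= 1).
#' @param group_means named list/vector of group-level means (baselines and
#'   `s_` shifts); defaults from [default_group_params()] are filled in for
#'   any omitted entry.
#' @param group_sds named list/vector of nonnegative group-level SDs,
#'   likewise completed from the defaults.
#' @param seed integer seed; per-subject substreams are derived
#'   deterministically from it.
#' @param model registered model name used to complete the defaults.
#' @return a list of class `ctx_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, model, group_means = list(),
                        group_sds = list(), seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  def <- default_group_params(model)
  means <- utils::modifyList(as.list(def$means), as.list(group_means))
  sds <- utils::modifyList(as.list(def$sds), as.list(group_sds))
  if (any(unlist(sds) < 0)) stop("group_sds must be nonnegative")
  info <- model_info(model)
  structure(list(n_subjects = as.integer(n_subjects), model = model,
                 means = means[info$all_pars], sds = sds[info$all_pars],
                 seed = as.integer(seed)),
            class = "ctx_cohort_spec")
}

#' Default group-level parameter distributions
#'
#' The generating distributions used for simulated cohorts.  Baseline means
#' are plausible mid-range values for regular gamblers on these tasks;
#' shift means use the fitted context effects reported for the respective
#' model class (discount-rate shift 0.77 under softmax and 0.40 under the
#' sigmoid DDM; learning-rate, beta-weight and drift-coefficient shifts
#' from the two-step models), so that simulated cohorts embody the
#' gambling-context effect the models are meant to recover.
#'
#' @param model registered model name.
#' @return list with named numeric vectors `means` and `sds` over the
#'   model's full parameter vector.
#' @export
default_group_params <- function(model) {
  info <- model_info(model)
  m <- switch(model,
    softmax = c(k_log = -3.5, beta = 0.15, s_k = 0.77, s_beta = 0.025),
    ddm0 = c(alpha = 1.6, tau = 0.35, z = 0.45, v = 0.3,
             s_alpha = 0.10, s_tau = -0.05, s_z = 0.02, s_v = 0),
    ddm_lin = c(k_log = -3.5, alpha = 1.6, tau = 0.35, z = 0.45,
                v_coeff = 0.08, s_k = 0.40, s_alpha = 0.10, s_tau = -0.05,
                s_z = 0.02, s_v_coeff = -0.012),
    ddm_s = c(k_log = -3.5, alpha = 1.6, tau = 0.35, z = 0.45,
              v_coeff = 0.15, v_max = 1.8, s_k = 0.40, s_alpha = 0.10,
              s_tau = -0.05, s_z = 0.02, s_v_coeff = -0.012,
              s_v_max = 0.33),
    softmax_hybrid = c(eta1 = 0.35, eta2 = 0.45, eta_decay = 0.60,
                       beta_mb = 4, beta_mf = 4, beta2 = 6, rho = 0.6,
                       s_eta1 = 0.44, s_eta2 = 0.40, s_eta_decay = 0,
                       s_beta_mb = 1.08, s_beta_mf = -1.14,
                       s_beta2 = -0.44, s_rho = 0.04),
    rlddm_lin = c(eta1 = 0.35, eta2 = 0.45, eta_decay = 0.60,
                  alpha_s1 = 2.2, alpha_s2 = 2.0, tau_s1 = 0.35,
                  tau_s2 = 0.30, vcoeff_mf = 1.5, vcoeff_mb = 3.0,
                  vcoeff_s2 = 6.0, rho = 0.3, s_eta1 = 0.08,
                  s_eta2 = 0.28, s_eta_decay = 0, s_alpha_s1 = -0.002,
                  s_alpha_s2 = 0.015, s_tau_s1 = 0.001, s_tau_s2 = 0.001,
                  s_vcoeff_mf = -0.93, s_vcoeff_mb = 2.0,
                  s_vcoeff_s2 = -0.64, s_rho = 0.05),
    rlddm_s = c(eta1 = 0.35, eta2 = 0.45, eta_decay = 0.60,
                alpha_s1 = 2.2, alpha_s2 = 2.0, tau_s1 = 0.35,
                tau_s2 = 0.30, vcoeff_mf = 1.5, vcoeff_mb = 3.0,
                vcoeff_s2 = 6.0, rho = 0.3, vmax_s1 = 2.5, vmax_s2 = 2.5,
                s_eta1 = 0.08, s_eta2 = 0.28, s_eta_decay = 0,
                s_alpha_s1 = -0.002, s_alpha_s2 = 0.015, s_tau_s1 = 0.001,
                s_tau_s2 = 0.001, s_vcoeff_mf = -0.93, s_vcoeff_mb = 4.01,
                s_vcoeff_s2 = -0.64, s_rho = 0.05, s_vmax_s1 = -0.19,
                s_vmax_s2 = 0.41),
    rlddm_null = c(alpha_s1 = 2.2, alpha_s2 = 2.0, tau_s1 = 0.35,
                   tau_s2 = 0.30, v_s1 = 0.5, v_s2 = 0.5,
                   s_alpha_s1 = 0, s_alpha_s2 = 0, s_tau_s1 = 0,
                   s_tau_s2 = 0, s_v_s1 = 0, s_v_s2 = 0),
    stop("no defaults for model '", model, "'")
  )
  s <- vapply(info$all_pars, function(p) {
    base <- sub("^s_", "", p)
    if (base %in% c("eta1", "eta2", "eta_decay", "z"))
      0.10
    else if (base %in% c("tau", "tau_s1", "tau_s2"))
      0.05
    else if (base %in% c("k_log"))
      0.8
    else if (base %in% c("beta", "v_coeff"))
      0.05
    else if (base %in% c("beta_mb", "beta_mf", "beta2", "vcoeff_mb",
                         "vcoeff_s2"))
      1.0
    else if (base %in% c("vcoeff_mf"))
      0.5
    else 0.3
  }, 0)
  if (any(!info$all_pars %in% names(m)))
    stop("internal: incomplete defaults for ", model)
  list(means = m[info$all_pars], sds = s)
}

## Draw per-subject parameter vectors (rows) from the group normals,
## redrawing any subject whose effective parameters leave the support.
.draw_subject_params <- function(spec) {
  info <- model_info(spec$model)
  mu <- unlist(spec$means)
  sd <- unlist(spec$sds)
  K <- length(info$pars)
  draw1 <- function() stats::rnorm(length(mu), mu, sd)
  ok <- function(th) {
    base <- th[seq_len(K)]; shift <- th[K + seq_len(K)]
    all(is.finite(.subject_support_penalty(info, base, shift)))
  }
  t(vapply(seq_len(spec$n_subjects), function(s) {
    for (i in 1:200) {
      th <- draw1()
      if (ok(th)) return(th)
    }
    stop("could not draw valid parameters for subject ", s,
         "; check group means/SDs against the parameter support")
  }, numeric(length(mu))))
}

## -Inf where an effective (baseline, baseline + shift) pair leaves the
## model's support; 0 otherwise.  Mirrors the compiled likelihood checks.
.subject_support_penalty <- function(info, base, shift) {
  names(base) <- info$pars
  eff <- rbind(base, base + shift)   # effective values at I = 0 and I = 1
  bad <- FALSE
  for (p in info$pars) {
    x <- eff[, p]
    bad <- bad || switch(p,
      z = any(x <= 0 | x >= 1),
      alpha = , alpha_s1 = , alpha_s2 = ,
      v_max = , vmax_s1 = , vmax_s2 = any(x <= 0),
      tau = , tau_s1 = , tau_s2 = any(x < 0),
      eta1 = , eta2 = , eta_decay = any(x < 0 | x > 1),
      FALSE)
  }
  if (bad) -Inf else 0
}

#' Simulate an intertemporal-choice cohort
#'
#' Subject-level parameters are drawn from the cohort's group
#' distributions; each subject completes one session per entry of the
#' design's `context_order` (task versions counterbalanced by the design).
#' Softmax agents produce choices only; DDM agents produce choices and RTs
#' by first-passage sampling.
#'
#' @param spec a [cohort_spec()] for a discounting model.
#' @param design a [make_discounting_design()] table (per-subject designs
#'   are re-shuffled copies with the same option sets).
#' @param model optional override of `spec$model`.
#' @param rt_method passed to [rwiener()].
#' @return data.frame of trials (`subject`, `session`, `context`, `trial`,
#'   amounts, `delay`, `choice`, `rt` in raw positive seconds) with the
#'   generating subject-level parameters in `attr(, "subject_params")`.
#' @export
simulate_discounting_cohort <- function(spec, design = NULL,
                                        model = spec$model,
                                        rt_method = "inverse") {
  stopifnot(inherits(spec, "ctx_cohort_spec"))
  info <- model_info(model)
  if (info$task != "discounting")
    stop("'", model, "' is not a discounting model")
  rng <- .local_rng(spec$seed)
  theta <- rng(.draw_subject_params(spec))
  colnames(theta) <- info$all_pars
  K <- length(info$pars)
  out <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    des <- if (is.null(design))
      make_discounting_design(version = 1 + (s %% 2),
                              seed = spec$seed + 7L * s) else design
    th <- theta[s, ]
    p <- as.list(th)
    sv <- subjective_value(des$ll_amount, des$delay, p$k_log %||% 0,
                           p$s_k %||% 0, des$context)
    rows <- rng({
      if (model == "softmax") {
        pr <- softmax_ll_probability(sv, p$beta, p$s_beta %||% 0,
                                     des$context)
        choice <- as.integer(stats::runif(nrow(des)) < pr)
        data.frame(des, choice = choice, rt = NA_real_)
      } else {
        drift <- switch(model,
          ddm0 = (p$v %||% 0) + (p$s_v %||% 0) * des$context,
          ddm_lin = drift_linear(sv, p$v_coeff, p$s_v_coeff %||% 0,
                                 des$context),
          ddm_s = drift_sigmoid(
            drift_linear(sv, p$v_coeff, p$s_v_coeff %||% 0, des$context),
            p$v_max, p$s_v_max %||% 0, des$context))
        a <- p$alpha + (p$s_alpha %||% 0) * des$context
        tau <- p$tau + (p$s_tau %||% 0) * des$context
        z <- p$z + (p$s_z %||% 0) * des$context
        srt <- vapply(seq_len(nrow(des)), function(t)
          rwiener(1, a[t], tau[t], z[t], drift[t], method = rt_method),
          0)
        data.frame(des, choice = as.integer(srt > 0), rt = abs(srt))
      }
    })
    rows <- data.frame(subject = s, rows)
    out[[s]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "subject_params") <- theta
  attr(res, "model") <- model
  res
}

#' Simulate a two-step cohort
#'
#' Full generative rollouts (MF/MB updating, decay, transition sampling,
#' reward delivery from the walks, and sampled per-stage RTs for RLDDM
#' agents).  Each subject completes one 300-trial session per context in
#' `context_order`; the second session uses the time-reversed walks
#' (paired-version mode).
#'
#' @param spec a [cohort_spec()] for a two-step model.
#' @param walks reward walks from [make_reward_walks()] (points scale);
#'   defaults to fresh walks from the spec seed.
#' @param structure a [transition_structure()].
#' @param model optional override of `spec$model`.
#' @param context_order session contexts (default `c(0, 1)`).
#' @param dt Euler step for RLDDM response-time sampling.
#' @return trial data.frame with walk-derived option rewards
#'   (`reward_s2_a1`, `reward_s2_a2`, points scale) alongside the delivered
#'   `reward`; generating parameters in `attr(, "subject_params")`.
#' @export
simulate_twostep_cohort <- function(spec, walks = NULL,
                                    structure = transition_structure(),
                                    model = spec$model,
                                    context_order = c(0, 1), dt = 1e-3) {
  stopifnot(inherits(spec, "ctx_cohort_spec"))
  info <- model_info(model)
  if (info$task != "twostep") stop("'", model, "' is not a two-step model")
  if (is.null(walks)) walks <- make_reward_walks(seed = spec$seed + 101L)
  rng <- .local_rng(spec$seed)
  theta <- rng(.draw_subject_params(spec))
  colnames(theta) <- info$all_pars
  n <- nrow(walks)
  walk_sets <- list(walks, walks[rev(seq_len(n)), , drop = FALSE])
  out <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    ord <- if (s %% 2 == 1) context_order else rev(context_order)
    wmat <- do.call(rbind, walk_sets[seq_along(ord)]) / 100
    I <- rep(ord, each = n)
    session <- rep(seq_along(ord), each = n)
    roll <- rng(.simulate_twostep_subject_cpp(info$id, theta[s, ], wmat,
                                              as.integer(I),
                                              as.integer(session),
                                              structure$p_common, dt, 30))
    visited <- cbind(2L * (roll$s2_state - 1L) + 1L,
                     2L * (roll$s2_state - 1L) + 2L)
    rows <- data.frame(subject = s, session = session, context = I,
                       trial = rep(seq_len(n), length(ord)),
                       s1_action = roll$s1,
                       transition = ifelse(roll$transition == 1, "common",
                                           "rare"),
                       s2_state = roll$s2_state, s2_action = roll$s2_action,
                       reward = roll$reward * 100,
                       reward_s2_a1 = wmat[cbind(seq_len(nrow(wmat)),
                                                 visited[, 1])] * 100,
                       reward_s2_a2 = wmat[cbind(seq_len(nrow(wmat)),
                                                 visited[, 2])] * 100,
                       rt_s1 = roll$rt_s1, rt_s2 = roll$rt_s2)
    out[[s]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "subject_params") <- theta
  attr(res, "model") <- model
  attr(res, "p_common") <- structure$p_common
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
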