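## Model registry: one entry per likelihood variant, keyed by the names used
## throughout the package.  `pars` lists the baseline parameters in the order
## expected by the compiled likelihoods; every baseline parameter x has an
## additive context-shift companion s_x, so a subject's full parameter vector
## is c(pars, paste0("s_", pars)).

.par_range <- function() {
  list(
    k_log     = c(-8, 1),
    beta      = c(0, 2),
    alpha     = c(0.05, 5),
    tau       = c(0.05, 2),
    z         = c(0.1, 0.9),
    v         = c(-5, 5),
    v_coeff   = c(0, 2),
    v_max     = c(0.1, 10),
    eta1      = c(0, 1),
    eta2      = c(0, 1),
    eta_decay = c(0, 1),
    beta_mb   = c(0, 20),
    beta_mf   = c(0, 20),
    beta2     = c(0, 20),
    rho       = c(-5, 5),
    alpha_s1  = c(0.05, 5),
    alpha_s2  = c(0.05, 5),
    tau_s1    = c(0.05, 2),
    tau_s2    = c(0.05, 2),
    vcoeff_mf = c(0, 20),
    vcoeff_mb = c(0, 20),
    vcoeff_s2 = c(0, 20),
    vmax_s1   = c(0.1, 10),
    vmax_s2   = c(0.1, 10),
    v_s1      = c(-5, 5),
    v_s2      = c(-5, 5)
  )
}

## default SD of the zero-centered Gaussian prior on group-level shift means;
## tighter for parameters living on a bounded (rate / probability / seconds)
## scale
.shift_prior_sd <- function(par) {
  tight <- c("eta1", "eta2", "eta_decay", "z", "tau", "tau_s1", "tau_s2")
  wide  <- c("beta_mb", "beta_mf", "beta2", "vcoeff_mf", "vcoeff_mb",
             "vcoeff_s2")
  ifelse(par %in% tight, 0.5, ifelse(par %in% wide, 5, 2))
}

.par_init <- function() {
  c(k_log = -3, beta = 0.1, alpha = 1.5, tau = 0.3, z = 0.5, v = 0,
    v_coeff = 0.1, v_max = 2, eta1 = 0.5, eta2 = 0.5, eta_decay = 0.6,
    beta_mb = 3, beta_mf = 3, beta2 = 3, rho = 0, alpha_s1 = 1.5,
    alpha_s2 = 1.5, tau_s1 = 0.3, tau_s2 = 0.3, vcoeff_mf = 2,
    vcoeff_mb = 2, vcoeff_s2 = 2, vmax_s1 = 2, vmax_s2 = 2,
    v_s1 = 0, v_s2 = 0)
}

.registry <- function() {
  list(
    softmax = list(task = "discounting", id = 0L,
                   pars = c("k_log", "beta")),
    ddm0 = list(task = "discounting", id = 1L,
                pars = c("alpha", "tau", "z", "v")),
    ddm_lin = list(task = "discounting", id = 2L,
                   pars = c("k_log", "alpha", "tau", "z", "v_coeff")),
    ddm_s = list(task = "discounting", id = 3L,
                 pars = c("k_log", "alpha", "tau", "z", "v_coeff", "v_max")),
    softmax_hybrid = list(task = "twostep", id = 0L,
                          pars = c("eta1", "eta2", "eta_decay", "beta_mb",
                                   "beta_mf", "beta2", "rho")),
    rlddm_lin = list(task = "twostep", id = 1L,
                     pars = c("eta1", "eta2", "eta_decay", "alpha_s1",
                              "alpha_s2", "tau_s1", "tau_s2", "vcoeff_mf",
                              "vcoeff_mb", "vcoeff_s2", "rho")),
    rlddm_s = list(task = "twostep", id = 2L,
                   pars = c("eta1", "eta2", "eta_decay", "alpha_s1",
                            "alpha_s2", "tau_s1", "tau_s2", "vcoeff_mf",
                            "vcoeff_mb", "vcoeff_s2", "rho", "vmax_s1",
                            "vmax_s2")),
    rlddm_null = list(task = "twostep", id = 3L,
                      pars = c("alpha_s1", "alpha_s2", "tau_s1", "tau_s2",
                               "v_s1", "v_s2"))
  )
}

#' Look up a model in the registry
#'
#' @param model one of `"softmax"`, `"ddm0"`, `"ddm_lin"`, `"ddm_s"`
#'   (intertemporal choice) or `"softmax_hybrid"`, `"rlddm_lin"`,
#'   `"rlddm_s"`, `"rlddm_null"` (two-step task).
#' @return a list with elements `task`, `id`, `pars` (baseline parameter
#'   names) and `all_pars` (baselines followed by their `s_` shifts).
#' @export
model_info <- function(model) {
  reg <- .registry()
  if (!model %in% names(reg))
    stop("unknown model '", model, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  info <- reg[[model]]
  info$model <- model
  info$all_pars <- c(info$pars, .shift_name(info$pars))
  info
}

## context-shift companion of a baseline parameter; the log discount rate's
## shift goes by its conventional name s_k
.shift_name <- function(par) ifelse(par == "k_log", "s_k",
                                    paste0("s_", par))

#' List the registered models
#'
#' @return character vector of model names, with the task as names attribute.
#' @export
list_models <- function() {
  reg <- .registry()
  structure(names(reg), task = vapply(reg, `[[`, "", "task"))
}
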