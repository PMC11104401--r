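## Reading/writing canonical trial tables and the end-to-end pipeline.

.schema_version <- 1L
.mandatory_cols <- list(
  discounting = c("subject", "context", "ll_amount", "delay", "choice"),
  twostep = c("subject", "context", "s1_action", "s2_state", "s2_action",
              "reward")
)

#' Write a canonical trial table
#'
#' CSV with a versioned schema comment header; generating parameters and
#' the seed (when supplied or carried as attributes) go to a JSON sidecar
#' `<path>.meta.json`.
#'
#' @param trials trial table.
#' @param path output CSV path.
#' @param task `"discounting"` or `"twostep"` (guessed from columns when
#'   omitted).
#' @param params optional generating parameters for the sidecar.
#' @param seed optional generating seed for the sidecar.
#' @return `path`, invisibly.
#' @export
write_choice_data <- function(trials, path, task = NULL, params = NULL,
                              seed = NULL) {
  task <- task %||% .guess_task(trials)
  con <- file(path, "w")
  writeLines(sprintf("# ctxshift schema=%d task=%s", .schema_version,
                     task), con)
  utils::write.csv(trials, con, row.names = FALSE)
  close(con)
  params <- params %||% attr(trials, "subject_params")
  if (!is.null(params) || !is.null(seed)) {
    meta <- list(schema = .schema_version, task = task, seed = seed,
                 model = attr(trials, "model"),
                 subject_params = if (!is.null(params)) as.data.frame(params))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

.guess_task <- function(trials) {
  if ("ll_amount" %in% names(trials)) "discounting"
  else if ("s1_action" %in% names(trials)) "twostep"
  else stop("cannot guess task from columns")
}

#' Read a choice-data file into the canonical schema
#'
#' Reads a delimited text file, renames columns via `schema_map`
#' (canonical name = source name), validates the mandatory columns for the
#' task, normalizes units (RTs to seconds, context to 0/1) and reports
#' unparseable rows with their line numbers.
#'
#' @param path CSV/TSV file; lines starting with `#` are ignored.
#' @param task `"discounting"` or `"twostep"`; guessed when omitted.
#' @param schema_map named character vector mapping canonical column names
#'   to the file's column names, for deposited data with unknown layouts.
#' @param rt_unit `"s"` (default) or `"ms"`.
#' @param sep field separator (default `","`).
#' @return canonical trial data.frame.
#' @examples
#' f <- system.file("extdata", "synthetic_discounting_example.csv",
#'                  package = "ctxshift")
#' head(read_choice_data(f))
#' @export
read_choice_data <- function(path, task = NULL, schema_map = NULL,
                             rt_unit = c("s", "ms"), sep = ",") {
  rt_unit <- match.arg(rt_unit)
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (!is.null(schema_map)) {
    for (canon in names(schema_map)) {
      src <- schema_map[[canon]]
      if (!src %in% names(d))
        stop("schema_map column '", src, "' not found in ", path)
      names(d)[names(d) == src] <- canon
    }
  }
  task <- task %||% .guess_task(d)
  miss <- setdiff(.mandatory_cols[[task]], names(d))
  if (length(miss))
    stop("missing mandatory column(s) for ", task, " data: ",
         paste(miss, collapse = ", "))
  if (is.character(d$context))
    d$context <- ifelse(tolower(d$context) %in%
                          c("1", "gambling", "gamble"), 1L, 0L)
  d$context <- as.integer(d$context)
  bad <- which(!d$context %in% c(0L, 1L) |
                 is.na(d[[.mandatory_cols[[task]][3]]]))
  if (length(bad))
    stop("unparseable row(s) at data line(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  for (col in intersect(c("rt", "rt_s1", "rt_s2"), names(d)))
    if (rt_unit == "ms") d[[col]] <- d[[col]] / 1000
  d
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> preprocess -> fit -> WAIC + directional BFs ->
#' posterior predictive check, writing all artifacts (trial table, summary
#' CSV, PPC CSV, log, JSON manifest with input hashes and software
#' versions) into the output directory.  Any stage failure aborts with the
#' stage name; artifacts produced so far are kept.
#'
#' @param config a list (or path to a YAML file) with entries `task`,
#'   `model`, `seed`, `out_dir`, and either `data` (a CSV path) or
#'   `simulate` (arguments for the cohort simulator: `n_subjects`, optional
#'   `group_means`, `group_sds`); optional `mcmc` (arguments to
#'   [mcmc_control()]), `priors`, `ppc_sims`.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  for (f in c("task", "model", "seed", "out_dir"))
    if (is.null(config[[f]])) stop("config is missing '", f, "'")
  info <- model_info(config$model)   # registry error before any compute
  if (info$task != config$task)
    stop("model '", config$model, "' does not belong to task '",
         config$task, "'")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out, "log.txt")
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
  stage <- function(name, expr) {
    log("stage %s: start", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log("ctxshift %s | R %s | seed %d",
      as.character(utils::packageVersion("ctxshift")),
      paste(R.version$major, R.version$minor, sep = "."),
      as.integer(config$seed))

  trials <- stage("simulate/load", {
    if (!is.null(config$data)) {
      read_choice_data(config$data, task = config$task,
                       schema_map = config$schema_map)
    } else {
      sim <- config$simulate
      if (is.null(sim)) stop("need either 'data' or 'simulate'")
      spec <- cohort_spec(sim$n_subjects %||% 10, config$model,
                          sim$group_means %||% list(),
                          sim$group_sds %||% list(),
                          seed = config$seed)
      if (config$task == "discounting")
        simulate_discounting_cohort(spec)
      else simulate_twostep_cohort(spec)
    }
  })
  trials <- stage("preprocess", {
    if (config$task == "discounting" && config$model != "softmax")
      preprocess_discounting_rts(trials)
    else if (config$task == "twostep" && config$model != "softmax_hybrid")
      preprocess_twostep_rts(trials)
    else trials
  })
  write_choice_data(trials, file.path(out, "trials.csv"),
                    task = config$task, seed = config$seed)

  fit <- stage("fit", {
    mc <- do.call(mcmc_control, config$mcmc %||% list())
    priors <- config$priors %||% ctx_priors(config$model)
    fit_hierarchical(config$model, trials, priors = priors, mcmc = mc,
                     seed = config$seed)
  })
  log("fit done: max R-hat %.3f (%s)", max(fit$rhat, na.rm = TRUE),
      if (fit$converged) "converged" else "flagged non-converged")

  stage("summaries", {
    s <- summary(fit)
    utils::write.csv(as.data.frame(s), file.path(out, "summary.csv"),
                     row.names = FALSE)
    w <- compute_waic(fit)
    utils::write.csv(data.frame(waic = w$waic, p_waic = w$p_waic,
                                lppd = w$lppd, se = w$se),
                     file.path(out, "waic.csv"), row.names = FALSE)
  })
  stage("ppc", {
    n_sims <- config$ppc_sims %||% 50
    ppc <- tryCatch({
      if (config$task == "discounting" && config$model != "softmax")
        ppc_discounting(fit, n_sims = n_sims, seed = config$seed)
      else if (config$task == "twostep")
        ppc_twostep(fit, n_sims = n_sims, seed = config$seed)
      else NULL
    }, error = function(e) { log("ppc skipped: %s",
                                 conditionMessage(e)); NULL })
    if (!is.null(ppc))
      utils::write.csv(ppc$bins, file.path(out, "ppc.csv"),
                       row.names = FALSE)
  })

  ## manifest: hash every artifact + the config fingerprint
  cfg_file <- file.path(out, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "priors")], cfg_file,
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- setdiff(list.files(out, full.names = TRUE),
                   file.path(out, "manifest.json"))
  manifest <- list(
    config_fingerprint = unname(tools::md5sum(cfg_file)),
    data_fingerprint = fit$fingerprint,
    seed = as.integer(config$seed),
    versions = list(ctxshift =
                      as.character(utils::packageVersion("ctxshift")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    artifacts = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log("pipeline complete: %d artifacts", length(files) + 1L)
  invisible(out)
}
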