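## Task designs: intertemporal-choice option sets, two-step reward walks and
## the 70/30 transition structure.

## the two counterbalanced option sets: 16 LL multipliers of the fixed 20
## euro SS reward, and 6 delays (days) per version; both multiplier sets
## average 32.405/16
.dd_multipliers <- list(
  `1` = c(1.05, 1.055, 1.15, 1.25, 1.35, 1.45, 1.55, 1.65, 1.85, 2.05,
          2.25, 2.55, 2.85, 3.05, 3.45, 3.85),
  `2` = c(1.025, 1.08, 1.2, 1.20, 1.33, 1.47, 1.5, 1.70, 1.83, 2.07, 2.3,
          2.5, 2.80, 3.10, 3.5, 3.80)
)
.dd_delays <- list(`1` = c(1, 7, 13, 31, 58, 122),
                   `2` = c(2, 6, 15, 29, 62, 118))
.dd_ss <- 20

#' Build an intertemporal-choice session design
#'
#' Generates the trial list for one or more sessions of the delay-discounting
#' task.  Each session crosses the 16 LL multipliers of its version with the
#' 6 delays (96 cells); a requested `n_trials` larger than the cross is
#' reached by uniform resampling of cells (with a message, since the
#' mechanism producing the task's printed 140 trials from 96 cells is not
#' recoverable).  Versions alternate across sessions starting from
#' `version`, mirroring the counterbalanced two-session design, and the
#' SS/LL screen side is randomized and recorded.
#'
#' @param version starting task version, 1 or 2.
#' @param context_order contexts of the successive sessions, a vector of 0
#'   (neutral) and 1 (gambling); one session is generated per element.
#' @param n_trials trials per session (default 140).
#' @param seed integer seed for shuffling and resampling.
#' @return data.frame with columns `session`, `context`, `trial`,
#'   `ss_amount`, `ll_amount`, `multiplier`, `delay`, `ll_on_left`.
#' @export
make_discounting_design <- function(version = 1, context_order = c(0, 1),
                                    n_trials = 140, seed = 1) {
  if (!version %in% c(1, 2)) stop("unknown version: ", version)
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (!all(context_order %in% c(0, 1)))
    stop("context_order must consist of 0s and 1s")
  rng <- .local_rng(seed)
  out <- vector("list", length(context_order))
  for (s in seq_along(context_order)) {
    v <- if (s %% 2 == 1) version else c(2, 1)[version]
    cross <- expand.grid(multiplier = .dd_multipliers[[as.character(v)]],
                         delay = .dd_delays[[as.character(v)]],
                         KEEP.OUT.ATTRS = FALSE)
    idx <- rng(sample.int(nrow(cross)))
    if (n_trials > nrow(cross)) {
      message("n_trials (", n_trials, ") exceeds the ", nrow(cross),
              "-cell multiplier x delay cross; resampling cells uniformly")
      idx <- c(idx, rng(sample.int(nrow(cross), n_trials - nrow(cross),
                                   replace = TRUE)))
    } else if (n_trials < nrow(cross)) {
      idx <- idx[seq_len(n_trials)]
    }
    cells <- cross[idx, , drop = FALSE]
    out[[s]] <- data.frame(
      session = s,
      context = context_order[s],
      version = v,
      trial = seq_len(n_trials),
      ss_amount = .dd_ss,
      ll_amount = .dd_ss * cells$multiplier,
      multiplier = cells$multiplier,
      delay = cells$delay,
      ll_on_left = rng(sample(c(TRUE, FALSE), n_trials, replace = TRUE)),
      row.names = NULL
    )
  }
  do.call(rbind, out)
}

#' Gaussian reward random walks with reflecting boundaries
#'
#' The four stage-2 reward series of the two-step task: Gaussian increments
#' (SD `step_sd` points) reflected at the bounds, emulating the task's walks
#' on 0-100 points.  With `reverse = TRUE` the time-reversed series are
#' returned, which is how the second task version relates to the first.
#'
#' @param n_trials length of the walks (default 300, the task length).
#' @param step_sd increment standard deviation in points.
#' @param bounds numeric length-2, reflecting boundaries.
#' @param seed integer seed.
#' @param reverse return the time-reversed walks.
#' @param start optional length-4 starting values; default uniform draws on
#'   the middle half of the range.
#' @return an `n_trials` x 4 matrix, columns named `s1a1`, `s1a2`, `s2a1`,
#'   `s2a2` (stage-2 state x action).
#' @export
make_reward_walks <- function(n_trials = 300, step_sd = 2.5,
                              bounds = c(0, 100), seed = 1, reverse = FALSE,
                              start = NULL) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (step_sd < 0) stop("step_sd must be nonnegative")
  if (length(bounds) != 2 || bounds[1] >= bounds[2])
    stop("invalid bounds: need lower < upper")
  rng <- .local_rng(seed)
  span <- bounds[2] - bounds[1]
  if (is.null(start))
    start <- rng(stats::runif(4, bounds[1] + span / 4, bounds[2] - span / 4))
  steps <- rng(matrix(stats::rnorm(n_trials * 4, 0, step_sd), n_trials, 4))
  walks <- matrix(NA_real_, n_trials, 4,
                  dimnames = list(NULL, c("s1a1", "s1a2", "s2a1", "s2a2")))
  x <- .reflect(start, bounds)
  walks[1, ] <- x
  for (t in seq_len(n_trials)[-1]) {
    x <- .reflect(x + steps[t, ], bounds)
    walks[t, ] <- x
  }
  if (reverse) walks <- walks[rev(seq_len(n_trials)), , drop = FALSE]
  walks
}

## standard reflecting-boundary construction: fold crossings back inside
.reflect <- function(x, bounds) {
  span <- 2 * (bounds[2] - bounds[1])
  y <- (x - bounds[1]) %% span
  y <- ifelse(y > span / 2, span - y, y)
  bounds[1] + y
}

#' Two-step transition structure
#'
#' @param p_common probability of the common transition (default 0.7).
#' @param mapping length-2 integer vector: preferred stage-2 state of each
#'   stage-1 action; the two actions must prefer different states.
#' @return a list of class `ctx_transitions`.
#' @export
transition_structure <- function(p_common = 0.7, mapping = c(1L, 2L)) {
  stopifnot(p_common >= 0, p_common <= 1)
  if (length(mapping) != 2 || mapping[1] == mapping[2] ||
      !all(mapping %in% 1:2))
    stop("mapping must assign the two actions to different stage-2 states")
  structure(list(p_common = p_common, mapping = as.integer(mapping)),
            class = "ctx_transitions")
}

#' Sample stage-2 states for stage-1 actions
#'
#' @param s1_action vector of stage-1 actions (1 or 2).
#' @param structure a [transition_structure()].
#' @param seed integer seed.
#' @return data.frame with `s2_state` and `transition`
#'   (`"common"`/`"rare"`).
#' @export
simulate_transition <- function(s1_action, structure = transition_structure(),
                                seed = 1) {
  if (!all(s1_action %in% 1:2)) stop("invalid stage-1 action")
  rng <- .local_rng(seed)
  common <- rng(stats::runif(length(s1_action))) < structure$p_common
  pref <- structure$mapping[s1_action]
  other <- structure$mapping[3 - s1_action]
  data.frame(s2_state = ifelse(common, pref, other),
             transition = ifelse(common, "common", "rare"))
}

## evaluate `expr` under a locally seeded RNG, leaving the caller's RNG
## state untouched
.local_rng <- function(seed) {
  force(seed)
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    seed <<- seed + 1L
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr
  }
}
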