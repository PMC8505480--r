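# 2IFC trial engine: three interleaved adaptive staircases on the
# 0-5% nominal contrast grid (0.1% steps). A correct response lowers the
# contrast; rule_k consecutive incorrect responses (3, 2 or 1 depending on
# the staircase) raise it.

CONTRAST_GRID_STEP <- 0.001
CONTRAST_GRID_MAX_INDEX <- 50L

#' Create a staircase state
#'
#' @param rule_k Consecutive incorrect responses required for an up step
#'   (1, 2 or 3).
#' @param start_level Starting index on the 0-5% contrast grid in 0.1% steps
#'   (0 to 50).
#' @param step Grid units moved per step (default 2 = 0.2% contrast).
#' @return An object of class `staircase_state`.
#' @export
staircase_new <- function(rule_k, start_level = 50L, step = 2L) {
  if (!rule_k %in% 1:3) stop("rule_k must be 1, 2 or 3")
  if (start_level < 0L || start_level > CONTRAST_GRID_MAX_INDEX) {
    stop("start_level must lie on the 0-50 grid")
  }
  structure(list(rule_k = as.integer(rule_k),
                 level_index = as.integer(start_level),
                 incorrect_run = 0L, step = as.integer(step),
                 history = list()),
            class = "staircase_state")
}

#' Current nominal contrast of a staircase
#' @param state A `staircase_state`.
#' @return Contrast on the 0.1% grid.
#' @export
staircase_contrast <- function(state) state$level_index * CONTRAST_GRID_STEP

#' Update a staircase after a response
#'
#' A correct response steps the level down and resets the incorrect-run
#' counter; an incorrect response increments the counter, and when it reaches
#' `rule_k` the level steps up and the counter resets. Levels are clamped to
#' the 0-50 grid.
#'
#' @param state A `staircase_state`.
#' @param correct Logical response correctness.
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, correct) {
  level <- state$level_index
  state$history[[length(state$history) + 1L]] <-
    c(level = level, correct = as.integer(correct))
  if (isTRUE(correct)) {
    state$level_index <- max(0L, level - state$step)
    state$incorrect_run <- 0L
  } else {
    state$incorrect_run <- state$incorrect_run + 1L
    if (state$incorrect_run >= state$rule_k) {
      state$level_index <- min(CONTRAST_GRID_MAX_INDEX, level + state$step)
      state$incorrect_run <- 0L
    }
  }
  state
}

#' Run a block of interleaved staircase trials
#'
#' Allocates `n_trials` equally across one staircase per up-rule, interleaves
#' them in seeded pseudorandom order, and on each trial presents the
#' staircase's current contrast to the observer callback.
#'
#' @param observer_callback Function `(nominal_contrast, target_interval)`
#'   returning a list with elements `response_interval` and `correct`.
#' @param rules Up-rules of the interleaved staircases (default `c(3, 2, 1)`).
#' @param n_trials Total trials; must divide evenly across staircases
#'   (default 120 = 40 per staircase).
#' @param start_levels Start grid index per staircase (default 50, 25, 50 for
#'   rules 3, 2, 1).
#' @param step Grid units per staircase step.
#' @param seed Integer seed controlling the interleave order and target
#'   intervals. `NULL` uses the current RNG state.
#' @return A data frame of trial records: `trial_index`, `staircase_id`,
#'   `rule_k`, `nominal_contrast`, `target_interval`, `response_interval`,
#'   `correct`.
#' @export
run_block <- function(observer_callback, rules = c(3L, 2L, 1L),
                      n_trials = 120L, start_levels = c(50L, 25L, 50L),
                      step = 2L, seed = NULL) {
  n_stairs <- length(rules)
  if (n_trials %% n_stairs != 0L) {
    stop("n_trials must be divisible by the number of staircases")
  }
  if (length(start_levels) != n_stairs) {
    stop("one start level per staircase required")
  }
  if (!is.null(seed)) set.seed(seed)
  stairs <- mapply(staircase_new, rules, start_levels,
                   MoreArgs = list(step = step), SIMPLIFY = FALSE)
  order <- sample(rep(seq_len(n_stairs), n_trials / n_stairs))
  targets <- sample(c(1L, 2L), n_trials, replace = TRUE)

  contrast <- numeric(n_trials)
  response <- integer(n_trials)
  correct <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    sid <- order[i]
    contrast[i] <- staircase_contrast(stairs[[sid]])
    res <- observer_callback(contrast[i], targets[i])
    response[i] <- as.integer(res$response_interval)
    correct[i] <- isTRUE(res$correct)
    stairs[[sid]] <- staircase_update(stairs[[sid]], correct[i])
  }
  data.frame(trial_index = seq_len(n_trials), staircase_id = order,
             rule_k = rules[order], nominal_contrast = contrast,
             target_interval = targets, response_interval = response,
             correct = correct)
}

#' Preliminary threshold from staircase reversals
#'
#' A reversal is a trial at which the movement direction of a staircase's
#' level changes sign. The preliminary nominal threshold is the mean contrast
#' over the last `last_r` reversals of each staircase, pooled across
#' staircases. This staircase-based estimate (not a psychometric fit) is the
#' one used to reconstruct at-threshold flicker spectra for the splatter
#' analysis.
#'
#' @param records Trial records as returned by [run_block()].
#' @param last_r Reversals retained per staircase (default 4).
#' @return Mean reversal contrast (on the 0.1% grid values).
#' @export
reversal_threshold <- function(records, last_r = 4L) {
  revs <- reversal_contrasts(records)
  picks <- lapply(names(revs), function(id) {
    if (length(revs[[id]]) < 2L) {
      stop("staircase ", id,
           " has fewer than 2 reversals; cannot form a preliminary threshold")
    }
    utils::tail(revs[[id]], last_r)
  })
  mean(unlist(picks))
}

# Per-staircase reversal contrasts: the level at each trial where the
# staircase's movement direction changes sign.
reversal_contrasts <- function(records) {
  lapply(split(records, records$staircase_id), function(d) {
    d <- d[order(d$trial_index), ]
    lv <- d$nominal_contrast
    dirs <- sign(diff(lv))
    rev_contrast <- numeric(0)
    last_dir <- 0
    for (i in seq_along(dirs)) {
      if (dirs[i] == 0) next
      if (last_dir != 0 && dirs[i] != last_dir) {
        rev_contrast <- c(rev_contrast, lv[i])
      }
      last_dir <- dirs[i]
    }
    rev_contrast
  })
}
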