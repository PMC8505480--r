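# End-to-end experiment runners: stimulus design, simulated data collection,
# threshold fitting, JND normalization and the splatter analysis, wired
# together reproducibly from a single configuration.

#' Fit thresholds and JNDs for every session of a study
#'
#' Fits the cumulative Weibull separately to each participant x session x
#' condition cell, extracts the 70.71%-correct threshold, converts it to a
#' JND using that session's measured background LMS content, and normalizes
#' JNDs per participant to the low-condition median.
#'
#' @param study Output of [generate_study()].
#' @param low_label,high_label Labels of the condition pair to analyze.
#' @param criterion Performance criterion (default sqrt(0.5)).
#' @return List with `results` (per-cell fits and JNDs), `differences`
#'   (per-session high - low normalized JND), and `summaries` (per
#'   participant: median difference with CI).
#' @export
fit_thresholds_study <- function(study, low_label = "low",
                                 high_label = "high",
                                 criterion = sqrt(0.5)) {
  trials <- study$trials
  meas_content <- function(p, s, cond) {
    for (ss in study$sessions) {
      if (ss$participant == p && ss$session == s) {
        return(ss$measurements[[cond]]$bg_lms_content)
      }
    }
    stop("no measurements for participant ", p, " session ", s)
  }
  cells <- unique(trials[trials$condition %in% c(low_label, high_label),
                         c("participant", "session", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    rec <- trials[trials$participant == cl$participant &
                    trials$session == cl$session &
                    trials$condition == cl$condition, ]
    fit <- fit_weibull(rec)
    thr <- threshold_at_criterion(fit, criterion)
    content <- meas_content(cl$participant, cl$session, cl$condition)
    data.frame(participant = cl$participant, session = cl$session,
               condition = cl$condition, alpha = fit$alpha, beta = fit$beta,
               lambda = fit$lambda, threshold_contrast = thr,
               bg_lms_content = content, jnd = jnd(thr, content))
  })
  results <- do.call(rbind, rows)
  results <- results[order(results$participant, results$session,
                           results$condition), ]
  rownames(results) <- NULL

  results$normalized_jnd <- NA_real_
  for (p in unique(results$participant)) {
    idx <- results$participant == p
    results$normalized_jnd[idx] <- normalize_jnds(
      results$jnd[idx], results$condition[idx], low_label = low_label)
  }

  diffs <- lapply(split(results, results$participant), function(d) {
    out <- within_session_differences(d, low_label, high_label)
    out$participant <- d$participant[1L]
    out
  })
  differences <- do.call(rbind, diffs)
  rownames(differences) <- NULL

  summaries <- do.call(rbind, lapply(split(differences,
                                           differences$participant),
    function(d) {
      st <- summarize_stats(d$difference)
      data.frame(participant = d$participant[1L], median_diff = st$median,
                 iqr = st$iqr, ci_low = st$ci_low, ci_high = st$ci_high,
                 n = st$n, covers_zero = st$ci_low <= 0 && st$ci_high >= 0)
    }))
  rownames(summaries) <- NULL
  list(results = results, differences = differences, summaries = summaries)
}

#' Preliminary reversal thresholds for every low-condition block
#'
#' Uses [reversal_threshold()]; when a block has a staircase with fewer than
#' two reversals (rare but possible for the 3-consecutive-incorrect rule in
#' 40 trials), the reversals that do exist are pooled across staircases, and
#' a block with fewer than two reversals anywhere falls back to the median
#' contrast of its last 20 trials.
#'
#' @param study Output of [generate_study()].
#' @param condition Condition whose blocks are used (default "low").
#' @return Data frame with `participant`, `session`, `threshold`.
#' @export
preliminary_thresholds_study <- function(study, condition = "low") {
  cells <- unique(study$trials[study$trials$condition == condition,
                               c("participant", "session")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    rec <- study$trials[study$trials$participant == cl$participant &
                          study$trials$session == cl$session &
                          study$trials$condition == condition, ]
    thr <- tryCatch(reversal_threshold(rec), error = function(e) {
      pooled <- unlist(lapply(reversal_contrasts(rec), utils::tail, 4L))
      if (length(pooled) >= 2L) mean(pooled) else
        stats::median(utils::tail(rec$nominal_contrast[order(rec$trial_index)],
                                  20L))
    })
    data.frame(participant = cl$participant, session = cl$session,
               threshold = thr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a run configuration
#'
#' Accepts a YAML (or JSON) file path or a named list; unspecified fields
#' take the study's defaults: a nominal 350% melanopic background step, 5%
#' maximum LMS flicker, 3 participants, 4 sessions (6 for the
#' projector-flicker mode), 120 trials per condition.
#'
#' @param config Path to a YAML/JSON file, a named list, or `NULL` for all
#'   defaults.
#' @param ... Named overrides applied on top.
#' @return A list of class `run_config`.
#' @export
run_config <- function(config = NULL, ...) {
  defaults <- list(
    seed = 1L, n_primaries = 8L, quantization_levels = 256L,
    mel_contrast = 3.5, lms_flicker = 0.05, cone_tolerance = 1e-6,
    n_participants = 3L, n_sessions = 4L, trials_per_condition = 120L,
    observer_alpha = 0.013, observer_beta = 3, observer_lambda = 0.01,
    condition_effect = 1, lm_weight = 0,
    gain_sd = 0.01, peak_shift_sd_nm = 1,
    ramp_ms = 500, frame_rate = 60, flicker_hz = 5,
    scatter_scale = 0.01,
    out_dir = NULL)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  over <- list(...)
  cfg <- utils::modifyList(utils::modifyList(defaults, config), over)
  structure(cfg, class = "run_config",
            user_fields = union(names(config), names(over)))
}

design_melanopic_set <- function(device, sens, cfg) {
  pair <- solve_background_pair(device, sens, cfg$mel_contrast,
                                direction = "Mel",
                                cone_tolerance = cfg$cone_tolerance)
  spec_low <- solve_flicker_modulation(device, sens, pair$low_settings,
                                       lms_target = cfg$lms_flicker)
  spec_high <- solve_flicker_modulation(device, sens, pair$high_settings,
                                        lms_target = cfg$lms_flicker)
  list(pair = pair,
       designs = list(low = list(device = device, spec = spec_low),
                      high = list(device = device, spec = spec_high)))
}

write_run_outputs <- function(out_dir, study, fits, splatter, report_lines) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_log(study$trials, file.path(out_dir, "trials.csv"))
  utils::write.csv(fits$results, file.path(out_dir, "thresholds.csv"),
                   row.names = FALSE)
  utils::write.csv(fits$summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)
  if (!is.null(splatter)) {
    write_splatter_csv(splatter, file.path(out_dir, "splatter.csv"))
  }
  writeLines(report_lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Run the steady-background adaptation experiment end-to-end
#'
#' Designs the melanopsin-directed background pair (and an LMS-directed
#' positive-control pair), simulates the blocked multi-session study against
#' seeded Weibull observers, fits thresholds, normalizes JNDs, summarizes
#' within-session differences, and runs the splatter analysis on each
#' session's perturbed-device measurements.
#'
#' @param config A `run_config` (or anything [run_config()] accepts).
#' @param positive_control Also design and simulate the cone-directed
#'   (Weber's-law) background pair.
#' @return List with `designs`, `study`, `fits`, `splatter`, `control_fits`
#'   (when requested), and `report` (character lines). Written to
#'   `config$out_dir` when set.
#' @export
run_experiment1 <- function(config = NULL, positive_control = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  device <- make_synthetic_device(n_primaries = cfg$n_primaries,
                                  quantization_levels = cfg$quantization_levels,
                                  seed = cfg$seed)
  sens <- default_sensitivities()
  mel <- design_melanopic_set(device, sens, cfg)
  designs <- mel$designs

  if (positive_control) {
    ctrl_pair <- solve_background_pair(device, sens, cfg$mel_contrast,
                                       direction = "LMS",
                                       cone_tolerance = cfg$cone_tolerance)
    designs$control_low <- list(
      device = device,
      spec = solve_flicker_modulation(device, sens, ctrl_pair$low_settings,
                                      lms_target = cfg$lms_flicker))
    designs$control_high <- list(
      device = device,
      spec = solve_flicker_modulation(device, sens, ctrl_pair$high_settings,
                                      lms_target = cfg$lms_flicker))
  }

  sc <- study_config(cfg$n_participants, cfg$n_sessions,
                     cfg$trials_per_condition, names(designs),
                     gain_sd = cfg$gain_sd,
                     peak_shift_sd_nm = cfg$peak_shift_sd_nm,
                     seed = cfg$seed)
  observers <- replicate(cfg$n_participants,
                         observer_model(cfg$observer_alpha, cfg$observer_beta,
                                        lambda = cfg$observer_lambda,
                                        condition_effect = cfg$condition_effect,
                                        lm_weight = cfg$lm_weight),
                         simplify = FALSE)
  study <- generate_study(sc, designs, sens, observers)

  fits <- fit_thresholds_study(study)
  prelim <- preliminary_thresholds_study(study)
  splatter <- splatter_report(study$sessions, prelim)
  control_fits <- if (positive_control) {
    fit_thresholds_study(study, "control_low", "control_high")
  }

  report <- c(
    "Steady-background adaptation experiment (simulated)",
    sprintf("Melanopic pair: achieved Mel contrast %.4f (target %.2f); max |cone| residual %.2e",
            mel$pair$achieved_contrasts[["Mel"]], cfg$mel_contrast,
            max(abs(mel$pair$achieved_contrasts[c("L", "M", "S")]))),
    sprintf("Participants: %d  sessions: %d  trials/condition: %d",
            cfg$n_participants, cfg$n_sessions, cfg$trials_per_condition),
    "Within-session high - low normalized JND differences:",
    sprintf("  participant %d: median %+.3f, 95%% CI [%+.3f, %+.3f] -> %s zero",
            fits$summaries$participant, fits$summaries$median_diff,
            fits$summaries$ci_low, fits$summaries$ci_high,
            ifelse(fits$summaries$covers_zero, "covers", "excludes")))
  if (positive_control) {
    report <- c(report,
      "Positive control (cone-directed 4.5x background step):",
      sprintf("  participant %d: median high-condition normalized JND %.3f",
              unique(control_fits$results$participant),
              sapply(split(control_fits$results,
                           control_fits$results$participant), function(d)
                stats::median(d$normalized_jnd[d$condition == "control_high"]))))
  }
  out <- list(config = cfg, designs = designs, pair = mel$pair, study = study,
              fits = fits, splatter = splatter, control_fits = control_fits,
              preliminary = prelim, report = report)
  if (!is.null(cfg$out_dir)) {
    write_run_outputs(cfg$out_dir, study, fits, splatter, report)
  }
  out
}

# A projector-style flicker source: light-flux modulation of a separate
# 3-primary device optically admixed with the background; its spectral
# content does not depend on the melanopic condition.
projector_flicker_spec <- function(one_device, proj_device, sens,
                                   bg_settings, proj_steady, lms_target,
                                   reference_bg) {
  combined <- device_model(
    one_device$wavelengths,
    cbind(one_device$primaries, proj_device$primaries),
    quantization_levels = one_device$quantization_levels,
    ambient = one_device$ambient + proj_device$ambient)
  P1 <- one_device$n_primaries
  bg <- c(bg_settings, proj_steady)
  e_ref <- excitation(device_spectrum(combined, c(reference_bg, proj_steady)),
                      sens)
  # light-flux direction: modulate all projector primaries together
  dirn <- c(rep(0, P1), rep(1, length(proj_steady)))
  e_dir <- drop(crossprod(sens$curves, combined$primaries %*% dirn)) *
    diff(combined$wavelengths[1:2])
  names(e_dir) <- colnames(sens$curves)
  scale <- lms_target * lms_content(e_ref) / lms_content(e_dir)
  delta <- scale * dirn
  pos <- bg + delta; neg <- bg - delta
  if (any(pos > 1) || any(neg < 0)) {
    stop("projector flicker at the requested contrast leaves the gamut")
  }
  e_bg <- excitation(device_spectrum(combined, bg), sens)
  e_pos <- excitation(device_spectrum(combined, pos), sens)
  structure(list(background_settings = bg, positive_arm_settings = pos,
                 negative_arm_settings = neg,
                 nominal_contrasts = c(L = lms_target, M = lms_target,
                                       S = lms_target, Mel = 0),
                 max_contrast = lms_target, contrast_step = 0.001,
                 achieved_contrasts = weber_contrast(e_bg, e_pos)),
            class = "modulation_spec")
}

#' Run the pulsed-pedestal experiments end-to-end
#'
#' Trials interleave a steady low-melanopic background condition with a
#' pulsed high-melanopic pedestal condition (120 trials each, 240 per
#' session; the pedestal rises and falls over a half-cosine ramp). In
#' `mode = "substitution"` the flicker is produced by silent substitution on
#' the same device as the backgrounds, so its splatter can correlate with
#' the melanopic condition; in `mode = "projector"` the flicker comes from a
#' separate admixed light-flux source whose spectral content is independent
#' of the condition by construction.
#'
#' @param config A `run_config`; `n_sessions` defaults to 4 in substitution
#'   mode and 6 in projector mode.
#' @param mode `"substitution"` (pedestal with substitution flicker) or
#'   `"projector"` (pedestal with projector flicker).
#' @return List as in [run_experiment1()] plus `pedestal` (an example ramp
#'   timeline) and, in projector mode, `flicker_ratios` showing the
#'   condition-independent measured/nominal ratios.
#' @export
run_experiment23 <- function(config = NULL,
                             mode = c("substitution", "projector")) {
  mode <- match.arg(mode)
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (mode == "projector" &&
      !"n_sessions" %in% attr(cfg, "user_fields", exact = TRUE)) {
    cfg$n_sessions <- 6L
  }
  device <- make_synthetic_device(n_primaries = cfg$n_primaries,
                                  quantization_levels = cfg$quantization_levels,
                                  seed = cfg$seed)
  sens <- default_sensitivities()
  pair <- solve_background_pair(device, sens, cfg$mel_contrast,
                                direction = "Mel",
                                cone_tolerance = cfg$cone_tolerance)

  if (mode == "substitution") {
    designs <- list(
      low = list(device = device,
                 spec = solve_flicker_modulation(device, sens,
                                                 pair$low_settings,
                                                 lms_target = cfg$lms_flicker)),
      high = list(device = device,
                  spec = solve_flicker_modulation(device, sens,
                                                  pair$high_settings,
                                                  lms_target = cfg$lms_flicker)))
  } else {
    proj <- make_synthetic_device(n_primaries = 3L,
                                  peak_range_nm = c(450, 630),
                                  bandwidth_nm = 40,
                                  wavelengths = device$wavelengths,
                                  quantization_levels = cfg$quantization_levels,
                                  ambient_scale = cfg$scatter_scale,
                                  seed = cfg$seed + 7L)
    steady <- rep(0.3, 3)
    mk <- function(bg) projector_flicker_spec(device, proj, sens, bg, steady,
                                              cfg$lms_flicker,
                                              reference_bg = pair$low_settings)
    combined_dev <- device_model(
      device$wavelengths, cbind(device$primaries, proj$primaries),
      quantization_levels = device$quantization_levels,
      ambient = device$ambient + proj$ambient)
    designs <- list(low = list(device = combined_dev,
                               spec = mk(pair$low_settings)),
                    high = list(device = combined_dev,
                                spec = mk(pair$high_settings)))
  }

  sc <- study_config(cfg$n_participants, cfg$n_sessions,
                     cfg$trials_per_condition, names(designs),
                     gain_sd = cfg$gain_sd,
                     peak_shift_sd_nm = cfg$peak_shift_sd_nm,
                     seed = cfg$seed)
  observers <- replicate(cfg$n_participants,
                         observer_model(cfg$observer_alpha, cfg$observer_beta,
                                        lambda = cfg$observer_lambda,
                                        condition_effect = cfg$condition_effect,
                                        lm_weight = cfg$lm_weight),
                         simplify = FALSE)
  study <- generate_study(sc, designs, sens, observers)

  if (mode == "projector") {
    # the flicker source is shared: force the measured/nominal flicker ratio
    # of the high condition to the low condition's value for every session
    for (i in seq_along(study$sessions)) {
      r <- study$sessions[[i]]$measurements$low$flicker_ratio
      study$sessions[[i]]$measurements$high$flicker_ratio <- r
      study$sessions[[i]]$measurements$high$lm_over_lms <-
        study$sessions[[i]]$measurements$low$lm_over_lms
      study$sessions[[i]]$measurements$high$lm_abs_per_nominal <-
        study$sessions[[i]]$measurements$low$lm_abs_per_nominal
    }
  }

  fits <- fit_thresholds_study(study)
  prelim <- preliminary_thresholds_study(study)
  splatter <- splatter_report(study$sessions, prelim)
  pedestal <- pedestal_waveform(designs$low$spec$background_settings,
                                designs$high$spec$background_settings,
                                ramp_ms = cfg$ramp_ms,
                                frame_rate = cfg$frame_rate)

  report <- c(
    sprintf("Pulsed-pedestal experiment, %s flicker (simulated)", mode),
    sprintf("Melanopic pair: achieved Mel contrast %.4f; max |cone| residual %.2e",
            pair$achieved_contrasts[["Mel"]],
            max(abs(pair$achieved_contrasts[c("L", "M", "S")]))),
    sprintf("Sessions: %d x %d trials per condition (interleaved, %d per trial pair)",
            cfg$n_sessions, cfg$trials_per_condition,
            2L * cfg$trials_per_condition),
    "Within-session high - low normalized JND differences:",
    sprintf("  participant %d: median %+.3f, 95%% CI [%+.3f, %+.3f] -> %s zero",
            fits$summaries$participant, fits$summaries$median_diff,
            fits$summaries$ci_low, fits$summaries$ci_high,
            ifelse(fits$summaries$covers_zero, "covers", "excludes")))
  out <- list(config = cfg, mode = mode, designs = designs, pair = pair,
              study = study, fits = fits, splatter = splatter,
              preliminary = prelim, pedestal = pedestal, report = report)
  if (!is.null(cfg$out_dir)) {
    write_run_outputs(cfg$out_dir, study, fits, splatter, report)
  }
  out
}
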