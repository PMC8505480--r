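# Synthetic stand-ins for everything the real study obtained from hardware
# and people: a multiprimary light source with calibration error (the origin
# of contrast "splatter"), and observers whose 2IFC detection follows a
# cumulative Weibull with a 50% guess rate.

#' Build a synthetic multiprimary device
#'
#' Gaussian-shaped primaries with peaks spread across `peak_range_nm`, plus
#' small seeded variation in peak position and amplitude so no two devices
#' are exactly alike. Deterministic given the seed.
#'
#' @param n_primaries Number of primaries (>= 3; >= 4 needed for silent
#'   substitution with four receptor classes).
#' @param peak_range_nm Range the primary peaks span (default 420-680 nm).
#' @param bandwidth_nm Gaussian sigma of each primary (default 30 nm).
#' @param wavelengths Wavelength grid.
#' @param quantization_levels Device settings resolution (default 256).
#' @param ambient_scale Scale of a small broadband ambient leak (default
#'   0.005 of a primary's peak power).
#' @param seed Integer seed.
#' @return A `device_model`.
#' @export
make_synthetic_device <- function(n_primaries = 8L,
                                  peak_range_nm = c(410, 650),
                                  bandwidth_nm = 14,
                                  wavelengths = default_wavelengths(),
                                  quantization_levels = 256L,
                                  ambient_scale = 0.005, seed = 1L) {
  if (n_primaries < 3L) stop("at least 3 primaries required")
  if (peak_range_nm[1] < min(wavelengths) || peak_range_nm[2] > max(wavelengths)) {
    stop("primary peaks must lie inside the wavelength grid")
  }
  set.seed(seed)
  peaks <- seq(peak_range_nm[1], peak_range_nm[2], length.out = n_primaries) +
    stats::rnorm(n_primaries, 0, 2)
  peaks <- pmin(max(wavelengths), pmax(min(wavelengths), peaks))
  amps <- exp(stats::rnorm(n_primaries, 0, 0.05))
  B <- sapply(seq_len(n_primaries), function(j) {
    amps[j] * exp(-0.5 * ((wavelengths - peaks[j]) / bandwidth_nm)^2)
  })
  ambient <- ambient_scale * exp(-0.5 * ((wavelengths - 550) / 120)^2)
  device_model(wavelengths, B, quantization_levels = quantization_levels,
               ambient = ambient)
}

#' Perturb a device to emulate calibration error
#'
#' Each primary is scaled by a lognormal gain factor and its spectrum shifted
#' in wavelength; the result plays the role of the physically measured device
#' whose output differs slightly from the nominal calibration, producing
#' contrast splatter on nominally silenced receptors.
#'
#' @param device A `device_model`.
#' @param gain_sd SD of the log gain (e.g. 0.01 for ~1% gain error).
#' @param peak_shift_sd_nm SD of the wavelength shift in nm.
#' @param seed Integer seed.
#' @return A new `device_model` with perturbed primaries.
#' @export
perturb_device <- function(device, gain_sd = 0.01, peak_shift_sd_nm = 1,
                           seed = 1L) {
  stopifnot(inherits(device, "device_model"))
  if (gain_sd < 0 || peak_shift_sd_nm < 0) stop("spreads must be nonnegative")
  set.seed(seed)
  P <- device$n_primaries
  gains <- exp(stats::rnorm(P, 0, gain_sd))
  shifts <- stats::rnorm(P, 0, peak_shift_sd_nm)
  wl <- device$wavelengths
  B <- sapply(seq_len(P), function(j) {
    shifted <- stats::approx(wl + shifts[j], device$primaries[, j],
                             xout = wl, rule = 2)$y
    gains[j] * pmax(shifted, 0)
  })
  device_model(wl, B, quantization_levels = device$quantization_levels,
               ambient = device$ambient)
}

#' Simulated Weibull observer
#'
#' Detection follows `p(c) = gamma + (1 - gamma - lambda) *
#' (1 - exp(-(c/alpha)^beta))` in the achieved LMS contrast `c`.
#' `condition_effect` multiplies alpha in the high-melanopic condition
#' (1 = no melanopsin effect, the study's null; 4.5 = a Weber's-law-sized
#' effect). `lm_weight` adds a chromatic-mediation term: the effective
#' contrast is `c_lms + lm_weight * |c_L - c_M|`, so splatter on the
#' sensitive L-M opponent mechanism can drive detection.
#'
#' @param alpha Threshold scale in contrast units (default 0.013, landing
#'   thresholds in the 1-2% range).
#' @param beta Slope (default 3).
#' @param gamma Guess rate (0.5 for 2IFC).
#' @param lambda Lapse rate in [0, 0.05].
#' @param condition_effect Multiplier on alpha in the high condition.
#' @param lm_weight Weight of |L - M| splatter in the effective contrast.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(alpha = 0.013, beta = 3, gamma = 0.5,
                           lambda = 0.01, condition_effect = 1,
                           lm_weight = 0) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (lambda < 0 || lambda > 0.05) stop("lambda must lie in [0, 0.05]")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda,
                 condition_effect = condition_effect, lm_weight = lm_weight),
            class = "observer_model")
}

#' Probability correct for a simulated observer
#' @param observer An `observer_model`.
#' @param contrast Achieved LMS contrast(s).
#' @param condition `"low"` or `"high"`; the high condition scales alpha by
#'   `condition_effect`.
#' @return Probability of a correct 2IFC response.
#' @export
observer_prob <- function(observer, contrast, condition = "low") {
  a <- observer$alpha *
    if (identical(condition, "high")) observer$condition_effect else 1
  weibull_prob(contrast, a, observer$beta, observer$gamma, observer$lambda)
}

#' Draw one 2IFC response from a simulated observer
#'
#' Correct with probability `p(c)`; an incorrect response reports the other
#' interval. Uses the current RNG state.
#'
#' @inheritParams observer_prob
#' @param target_interval 1 or 2.
#' @return List with `response_interval` and `correct`.
#' @export
observer_response <- function(observer, contrast, target_interval,
                              condition = "low") {
  p <- observer_prob(observer, contrast, condition)
  correct <- stats::runif(1) < p
  list(response_interval = if (correct) target_interval else 3L - as.integer(target_interval),
       correct = correct)
}

# Achieved-stimulus properties of one condition on the measured device:
# backgrounds rendered from nominal settings on the perturbed device, the
# ratio of measured to nominal flicker LMS contrast, and the chromatic
# splatter ratio of the measured flicker.
measure_condition <- function(nominal_device, measured_device, sens, spec,
                              probe_contrast = NULL) {
  if (is.null(probe_contrast)) probe_contrast <- spec$max_contrast
  bg_meas <- device_spectrum(measured_device, spec$background_settings)
  e_bg <- excitation(bg_meas, sens)
  sc <- scale_modulation(spec, probe_contrast)
  e_pos <- excitation(device_spectrum(measured_device, sc$positive_settings), sens)
  meas_lms <- lms_contrast(e_bg, e_pos)
  ratio <- meas_lms / sc$snapped_contrast
  lm_ratio <- lm_over_lms(e_bg, e_pos)
  lm_abs <- abs(weber_contrast(e_bg, e_pos)[["L"]] -
                weber_contrast(e_bg, e_pos)[["M"]])
  list(background_spectrum = bg_meas, bg_lms_content = lms_content(e_bg),
       bg_excitations = e_bg, flicker_ratio = ratio,
       lm_over_lms = lm_ratio,
       lm_abs_per_nominal = lm_abs / sc$snapped_contrast)
}

#' Simulate one experimental session
#'
#' Runs the staircase-driven 2IFC engine against a simulated observer for
#' each condition. The observer responds to the achieved LMS contrast of the
#' stimulus as rendered on the session's measured (perturbed) device, so
#' device imprecision feeds through to behavior; the session also emits the
#' measured stimulus properties needed by the splatter analysis.
#'
#' @param designs Named list, one entry per condition (e.g. `low`, `high`),
#'   each a list with elements `spec` (a `modulation_spec`) and the nominal
#'   `device`.
#' @param observer An `observer_model`.
#' @param measured_device The session's perturbed device (defaults to the
#'   nominal device of each design: no splatter).
#' @param sens A `receptor_sensitivities`.
#' @param n_trials Trials per condition (default 120).
#' @param seed Integer seed for this session.
#' @return List with `trials` (one data frame, a `condition` column added)
#'   and `measurements` (per-condition achieved-stimulus properties).
#' @export
generate_session <- function(designs, observer, sens, measured_device = NULL,
                             n_trials = 120L, seed = 1L) {
  trials <- list()
  measurements <- list()
  for (i in seq_along(designs)) {
    cond <- names(designs)[i]
    des <- designs[[i]]
    mdev <- if (is.null(measured_device)) des$device else measured_device
    meas <- measure_condition(des$device, mdev, sens, des$spec)
    measurements[[cond]] <- meas
    eff_gain <- meas$flicker_ratio +
      observer$lm_weight * meas$lm_abs_per_nominal
    cb <- function(contrast, target_interval) {
      observer_response(observer, contrast * eff_gain, target_interval,
                        condition = cond)
    }
    rec <- run_block(cb, n_trials = n_trials, seed = seed + i)
    rec$condition <- cond
    trials[[cond]] <- rec
  }
  list(trials = do.call(rbind, trials), measurements = measurements)
}

#' Study configuration
#'
#' @param n_participants Number of simulated participants.
#' @param n_sessions Valid sessions per participant (4 for the adaptation
#'   experiment, 6 for the projector-flicker experiment).
#' @param trials_per_condition Trials per condition per session (120).
#' @param conditions Condition labels.
#' @param gain_sd,peak_shift_sd_nm Session-to-session device calibration
#'   error feeding the splatter analysis.
#' @param seed Master seed; per-participant and per-session seeds are spawned
#'   from it deterministically.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_participants = 3L, n_sessions = 4L,
                         trials_per_condition = 120L,
                         conditions = c("low", "high"),
                         gain_sd = 0.01, peak_shift_sd_nm = 1,
                         seed = 1L) {
  stopifnot(n_participants >= 1L, n_sessions >= 1L,
            trials_per_condition >= 3L)
  structure(list(n_participants = as.integer(n_participants),
                 n_sessions = as.integer(n_sessions),
                 trials_per_condition = as.integer(trials_per_condition),
                 conditions = conditions, gain_sd = gain_sd,
                 peak_shift_sd_nm = peak_shift_sd_nm,
                 seed = as.integer(seed)),
            class = "study_config")
}

spawn_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(2^31 - 2, n)
}

#' Simulate a full multi-participant study
#'
#' Loops [generate_session()] over participants and sessions. Each session
#' gets its own perturbed device (calibration drifts between sessions), and
#' each participant its own observer. Deterministic given the master seed.
#'
#' @param config A `study_config`.
#' @param designs Per-condition designs as in [generate_session()].
#' @param sens A `receptor_sensitivities`.
#' @param observers Optional list of `observer_model`s, one per participant;
#'   defaults to identical default observers.
#' @return List with `trials` (single data frame with `participant` and
#'   `session` columns) and `sessions` (nested per-session measurement
#'   records).
#' @export
generate_study <- function(config, designs, sens, observers = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(observers)) {
    observers <- replicate(config$n_participants, observer_model(),
                           simplify = FALSE)
  }
  nominal_device <- designs[[1L]]$device
  n_cells <- config$n_participants * config$n_sessions
  seeds <- spawn_seeds(config$seed, 2L * n_cells)
  trials <- list(); sessions <- list()
  cell <- 0L
  for (p in seq_len(config$n_participants)) {
    for (s in seq_len(config$n_sessions)) {
      cell <- cell + 1L
      mdev <- perturb_device(nominal_device, config$gain_sd,
                             config$peak_shift_sd_nm, seed = seeds[cell])
      ses <- generate_session(designs, observers[[p]], sens,
                              measured_device = mdev,
                              n_trials = config$trials_per_condition,
                              seed = seeds[n_cells + cell])
      ses$trials$participant <- p
      ses$trials$session <- s
      trials[[cell]] <- ses$trials
      sessions[[cell]] <- list(participant = p, session = s,
                               measurements = ses$measurements,
                               measured_device = mdev)
    }
  }
  out <- do.call(rbind, trials)
  rownames(out) <- NULL
  list(trials = out, sessions = sessions, config = config)
}

# ---- trial-log CSV ----------------------------------------------------------

TRIAL_LOG_COLS <- c("participant", "session", "experiment", "condition",
                    "trial_index", "staircase_id", "nominal_contrast",
                    "target_interval", "response_interval", "correct")

#' Read / write trial logs as CSV
#'
#' Columns: participant, session, experiment, condition, trial_index,
#' staircase_id, nominal_contrast, target_interval, response_interval,
#' correct.
#'
#' @param trials Trial data frame.
#' @param path File path.
#' @param experiment Experiment label filled in when the data frame lacks an
#'   `experiment` column.
#' @name trial_log
#' @export
write_trial_log <- function(trials, path, experiment = "exp1") {
  if (!"experiment" %in% names(trials)) trials$experiment <- experiment
  if (!"participant" %in% names(trials)) trials$participant <- 1L
  if (!"session" %in% names(trials)) trials$session <- 1L
  missing <- setdiff(TRIAL_LOG_COLS, names(trials))
  if (length(missing)) stop("trial log lacks columns: ",
                            paste(missing, collapse = ", "))
  utils::write.csv(trials[TRIAL_LOG_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname trial_log
#' @export
read_trial_log <- function(path) {
  d <- utils::read.csv(path, check.names = TRUE)
  missing <- setdiff(TRIAL_LOG_COLS, names(d))
  if (length(missing)) stop("trial log lacks columns: ",
                            paste(missing, collapse = ", "))
  d$correct <- as.logical(d$correct)
  d
}
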