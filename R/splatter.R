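# Artifact-prediction analyses: convert measured-vs-nominal stimulus
# deviations into the normalized JNDs that would be observed if melanopsin
# had no effect on sensitivity and detection were mediated by (a) background
# cone content under Weber's law, (b) achieved rather than nominal flicker
# contrast, or (c) the L-M chromatic splatter of the flicker.

normalize_pair <- function(jnd_low, jnd_high) {
  m <- stats::median(jnd_low)
  if (!is.finite(m) || m <= 0) stop("low-condition predicted JNDs must have a positive median")
  list(low = jnd_low / m, high = jnd_high / m)
}

#' Predicted JNDs from background splatter (Weber's-law predictor)
#'
#' Assumes melanopsin has no effect: the low-condition nominal threshold
#' contrast is taken as the threshold on both backgrounds, and multiplied by
#' each background's measured content to give predicted JNDs, normalized so
#' the low-condition median is 1. Fed the cone (LMS) contents of a
#' well-silenced pair this predicts ~1 in both conditions; fed the melanopsin
#' excitations of a 350%-contrast pair it returns the Weber's-law upper bound
#' of 4.5 in the high condition.
#'
#' @param nominal_threshold_low Nominal threshold contrast(s) measured in the
#'   low condition (scalar or one per session).
#' @param measured_bg_low,measured_bg_high Measured background content per
#'   session (any mechanism's excitation/content).
#' @return Data frame with columns `session`, `pred_low`, `pred_high`
#'   (normalized predicted JNDs).
#' @export
predict_jnd_background_splatter <- function(nominal_threshold_low,
                                            measured_bg_low,
                                            measured_bg_high) {
  n <- length(measured_bg_low)
  if (length(measured_bg_high) != n) {
    stop("need one measured background per condition per session")
  }
  if (any(!is.finite(measured_bg_low)) || any(!is.finite(measured_bg_high))) {
    stop("missing background measurement")
  }
  thr <- rep_len(nominal_threshold_low, n)
  nn <- normalize_pair(thr * measured_bg_low, thr * measured_bg_high)
  data.frame(session = seq_len(n), pred_low = nn$low, pred_high = nn$high)
}

#' Predicted JNDs from flicker splatter
#'
#' The low-condition nominal threshold is carried to both conditions, scaled
#' by each condition's measured/nominal flicker LMS contrast ratio (giving
#' the achieved contrast at the nominal threshold), then converted to a JND
#' with the measured background content and normalized.
#'
#' @inheritParams predict_jnd_background_splatter
#' @param ratio_low,ratio_high Measured/nominal flicker LMS contrast ratio
#'   per session, > 0.
#' @return Data frame with `session`, `pred_low`, `pred_high`.
#' @export
predict_jnd_flicker_splatter <- function(nominal_threshold_low,
                                         ratio_low, ratio_high,
                                         measured_bg_low, measured_bg_high) {
  n <- length(ratio_low)
  if (length(ratio_high) != n) stop("need one flicker ratio per condition per session")
  if (any(ratio_low <= 0) || any(ratio_high <= 0)) {
    stop("measured/nominal flicker ratios must be positive")
  }
  thr <- rep_len(nominal_threshold_low, n)
  nn <- normalize_pair(thr * ratio_low * rep_len(measured_bg_low, n),
                       thr * ratio_high * rep_len(measured_bg_high, n))
  data.frame(session = seq_len(n), pred_low = nn$low, pred_high = nn$high)
}

#' Predicted JNDs under L-M chromatic mediation
#'
#' Assumes detection is mediated exclusively by the L-M chromatic splatter of
#' the flicker: the absolute measured L-M contrast at the low-condition
#' threshold is held constant across conditions, and each condition's
#' (L-M)/LMS splatter ratio converts it back to the nominal LMS contrast that
#' would reach that L-M contrast there. Greater chromatic splatter in the
#' high condition therefore predicts a lower threshold (higher sensitivity)
#' under the null.
#'
#' @inheritParams predict_jnd_background_splatter
#' @param measured_lm_at_threshold_low Absolute measured L-M contrast of the
#'   flicker at the low-condition threshold, per session.
#' @param lm_over_lms_low,lm_over_lms_high (L-M)/LMS splatter ratio per
#'   session; must be nonzero.
#' @return Data frame with `session`, `pred_low`, `pred_high`.
#' @export
predict_jnd_lm_mediation <- function(measured_lm_at_threshold_low,
                                     lm_over_lms_low, lm_over_lms_high,
                                     measured_bg_low, measured_bg_high) {
  n <- length(lm_over_lms_low)
  if (length(lm_over_lms_high) != n) stop("need one L-M ratio per condition per session")
  if (any(lm_over_lms_low == 0) || any(lm_over_lms_high == 0)) {
    stop("(L-M)/LMS ratio of zero: L-M mediation impossible")
  }
  lm_thr <- abs(rep_len(measured_lm_at_threshold_low, n))
  thr_low <- lm_thr / abs(lm_over_lms_low)
  thr_high <- lm_thr / abs(lm_over_lms_high)
  nn <- normalize_pair(thr_low * rep_len(measured_bg_low, n),
                       thr_high * rep_len(measured_bg_high, n))
  data.frame(session = seq_len(n), pred_low = nn$low, pred_high = nn$high)
}

#' Standard error of the median
#'
#' Normal-theory approximation `1.2533 * sd / sqrt(n)`.
#' @param values Numeric vector.
#' @return Scalar standard error.
#' @export
se_median <- function(values) 1.2533 * stats::sd(values) / sqrt(length(values))

#' Full splatter report for a set of sessions
#'
#' For each session, renders the nominal stimulus settings through that
#' session's measured (perturbed) device, computes the measured background
#' LMS contents, measured/nominal flicker contrast ratios and (L-M)/LMS
#' splatter ratios, and runs all three artifact predictors using the
#' session's preliminary (staircase-reversal) threshold.
#'
#' @param sessions Per-session records as produced by [generate_study()]
#'   (`$sessions`): each has `participant`, `session` and `measurements`
#'   with `low` and `high` entries.
#' @param preliminary_thresholds Data frame with columns `participant`,
#'   `session`, `threshold` (nominal low-condition preliminary threshold from
#'   [reversal_threshold()]).
#' @return List with `per_session` (one row per session: measured quantities
#'   and the three predictions for both conditions) and `per_participant`
#'   (medians with standard errors of the median).
#' @export
splatter_report <- function(sessions, preliminary_thresholds) {
  rows <- lapply(sessions, function(ss) {
    ml <- ss$measurements$low; mh <- ss$measurements$high
    if (is.null(ml) || is.null(mh)) {
      stop("session ", ss$session, " lacks low/high measurements")
    }
    thr <- preliminary_thresholds$threshold[
      preliminary_thresholds$participant == ss$participant &
        preliminary_thresholds$session == ss$session]
    if (length(thr) != 1L) {
      stop("no unique preliminary threshold for participant ", ss$participant,
           " session ", ss$session)
    }
    data.frame(participant = ss$participant, session = ss$session,
               threshold = thr,
               bg_lms_low = ml$bg_lms_content, bg_lms_high = mh$bg_lms_content,
               flicker_ratio_low = ml$flicker_ratio,
               flicker_ratio_high = mh$flicker_ratio,
               lm_over_lms_low = ml$lm_over_lms,
               lm_over_lms_high = mh$lm_over_lms,
               lm_abs_low = ml$lm_abs_per_nominal,
               lm_abs_high = mh$lm_abs_per_nominal)
  })
  d <- do.call(rbind, rows)

  per_part <- lapply(split(d, d$participant), function(p) {
    bg <- predict_jnd_background_splatter(p$threshold, p$bg_lms_low, p$bg_lms_high)
    fl <- predict_jnd_flicker_splatter(p$threshold, p$flicker_ratio_low,
                                       p$flicker_ratio_high,
                                       p$bg_lms_low, p$bg_lms_high)
    lm_at_thr <- p$lm_abs_low * p$threshold * p$flicker_ratio_low
    lm <- if (all(abs(c(p$lm_over_lms_low, p$lm_over_lms_high)) < 1e-9)) {
      # below numerical silence there is no chromatic route: the null
      # prediction is exactly no difference between conditions
      data.frame(session = seq_len(nrow(p)), pred_low = rep(1, nrow(p)),
                 pred_high = rep(1, nrow(p)))
    } else {
      predict_jnd_lm_mediation(lm_at_thr, p$lm_over_lms_low,
                               p$lm_over_lms_high,
                               p$bg_lms_low, p$bg_lms_high)
    }
    p$pred_bg_low <- bg$pred_low;  p$pred_bg_high <- bg$pred_high
    p$pred_flicker_low <- fl$pred_low;  p$pred_flicker_high <- fl$pred_high
    p$pred_lm_low <- lm$pred_low;  p$pred_lm_high <- lm$pred_high
    p
  })
  per_session <- do.call(rbind, per_part)
  rownames(per_session) <- NULL

  summ <- lapply(split(per_session, per_session$participant), function(p) {
    med_se <- function(v) c(stats::median(v), se_median(v))
    vals <- sapply(c("pred_bg_low", "pred_bg_high", "pred_flicker_low",
                     "pred_flicker_high", "pred_lm_low", "pred_lm_high",
                     "flicker_ratio_low", "flicker_ratio_high",
                     "lm_over_lms_low", "lm_over_lms_high"),
                   function(col) med_se(p[[col]]))
    data.frame(participant = p$participant[1L],
               stat = c("median", "se_median"), vals, check.names = FALSE)
  })
  per_participant <- do.call(rbind, summ)
  rownames(per_participant) <- NULL
  list(per_session = per_session, per_participant = per_participant)
}

#' Write / read the splatter per-session CSV
#' @param report A splatter report (from [splatter_report()]).
#' @param path File path.
#' @name splatter_csv
#' @export
write_splatter_csv <- function(report, path) {
  utils::write.csv(report$per_session, path, row.names = FALSE)
  invisible(path)
}

#' @rdname splatter_csv
#' @export
read_splatter_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
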