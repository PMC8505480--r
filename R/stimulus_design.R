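# Silent-substitution stimulus design on a multiprimary device model.
#
# The device output is linear in its settings: spectrum = B %*% s + ambient,
# with s in [0,1]^P. Receptor excitations are therefore linear in s, so once
# a target Weber contrast is fixed every design constraint is linear and the
# solver reduces to an equality-constrained least-norm problem (closed-form
# KKT solve), with a penalized box-constrained refinement when the unconstrained
# solution leaves the gamut.

#' Construct a multiprimary device model
#'
#' @param wavelengths Uniform wavelength grid in nm.
#' @param primaries Numeric matrix, one column per primary, giving the
#'   spectral power emitted at full setting (power units per unit setting).
#' @param quantization_levels Number of uniform settings levels the device
#'   can realize (e.g. 256 for 8-bit control); `Inf` for an ideal device.
#' @param ambient A `spectral_samples` object (or power vector) added to
#'   every output: the fixed scatter/leak component.
#' @return An object of class `device_model`.
#' @export
device_model <- function(wavelengths, primaries,
                         quantization_levels = Inf, ambient = NULL) {
  wavelengths <- as.numeric(wavelengths)
  check_uniform_grid(wavelengths)
  primaries <- as.matrix(primaries)
  if (nrow(primaries) != length(wavelengths)) {
    stop("primaries must have one row per wavelength sample")
  }
  if (any(primaries < 0)) stop("primary spectra must be nonnegative")
  if (is.null(ambient)) {
    ambient <- numeric(length(wavelengths))
  } else if (inherits(ambient, "spectral_samples")) {
    check_same_grid(wavelengths, ambient$wavelengths, "device", "ambient")
    ambient <- ambient$power
  } else {
    ambient <- as.numeric(ambient)
    if (length(ambient) != length(wavelengths)) {
      stop("ambient power vector length does not match the device grid")
    }
  }
  if (any(ambient < 0)) stop("ambient power must be nonnegative")
  structure(list(wavelengths = wavelengths, primaries = primaries,
                 n_primaries = ncol(primaries),
                 quantization_levels = quantization_levels,
                 ambient = ambient),
            class = "device_model")
}

#' @export
print.device_model <- function(x, ...) {
  cat(sprintf("<device_model> %d primaries on %d-sample grid, %s quantization, ambient power %.4g\n",
              x$n_primaries, length(x$wavelengths),
              if (is.finite(x$quantization_levels))
                sprintf("%d-level", x$quantization_levels) else "continuous",
              sum(x$ambient)))
  invisible(x)
}

#' Quantize device settings
#'
#' Rounds each setting to the nearest of `quantization_levels` uniform steps
#' in [0, 1] and clamps to the gamut.
#'
#' @param settings Settings vector.
#' @param levels Number of levels; `Inf` returns the clamped input.
#' @return Quantized settings in [0, 1].
#' @export
quantize_settings <- function(settings, levels) {
  s <- pmin(1, pmax(0, settings))
  if (!is.finite(levels)) return(s)
  round(s * (levels - 1)) / (levels - 1)
}

#' Render device output for a settings vector
#'
#' @param device A `device_model`.
#' @param settings Settings in [0, 1]^P.
#' @param quantize Apply the device's settings quantization before rendering.
#' @return A `spectral_samples` object (primaries x settings + ambient).
#' @export
device_spectrum <- function(device, settings, quantize = FALSE) {
  stopifnot(inherits(device, "device_model"))
  settings <- as.numeric(settings)
  if (length(settings) != device$n_primaries) {
    stop("settings length must equal the number of primaries")
  }
  if (any(settings < -1e-9 | settings > 1 + 1e-9)) {
    stop("settings outside the device gamut [0, 1]")
  }
  if (quantize) settings <- quantize_settings(settings, device$quantization_levels)
  power <- drop(device$primaries %*% pmin(1, pmax(0, settings))) + device$ambient
  spectral_samples(device$wavelengths, pmax(power, 0))
}

# Receptor-excitation rows for the primaries (labels x P) and the ambient
# excitation vector; everything downstream is linear algebra on these.
receptor_rows <- function(device, sens) {
  check_same_grid(device$wavelengths, sens$wavelengths, "device", "sensitivity")
  dl <- device$wavelengths[2L] - device$wavelengths[1L]
  R <- crossprod(sens$curves, device$primaries) * dl   # 4 x P
  rownames(R) <- colnames(sens$curves)
  list(R = R, ambient = excitation(device$ambient, sens))
}

# Least-norm solution of A x = b nearest x0, then (if the box is violated)
# a penalized L-BFGS-B refinement followed by a projection back onto the
# equality manifold. Returns NULL when no solution fits the box.
solve_linear_design <- function(A, b, x0, lower, upper, tol = 1e-8) {
  AAt <- tcrossprod(A)
  x <- x0 + drop(crossprod(A, solve(AAt, b - drop(A %*% x0))))
  slack <- 1e-9
  if (all(x >= lower - slack & x <= upper + slack)) {
    return(x)
  }
  obj <- function(z, w) sum((z - x0)^2) + w * sum((drop(A %*% z) - b)^2)
  z <- pmin(upper, pmax(lower, x))
  for (w in c(1e4, 1e6, 1e8)) {
    fit <- stats::optim(z, obj, w = w, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500))
    z <- fit$par
  }
  # project back onto the equality manifold (with one refinement pass) and
  # re-check the box
  for (i in 1:3) z <- z + drop(crossprod(A, solve(AAt, b - drop(A %*% z))))
  if (all(z >= lower - tol & z <= upper + tol)) {
    return(z)
  }
  NULL
}

#' Design a silent-substitution background pair
#'
#' Finds low- and high-excitation background settings whose exchange delivers
#' a target Weber contrast on one receptor mechanism (melanopsin by default)
#' while silencing the complementary mechanisms (the L, M and S cones for a
#' melanopsin-directed pair). With the target fixed, all constraints are
#' linear in the stacked settings vector (s_low, s_high), and the pair
#' closest to a preferred operating point is returned. When the target is
#' infeasible within the gamut the maximal achievable contrast is found by
#' bisection and returned with a warning.
#'
#' Both settings keep a margin from the gamut edges so that +/- max-contrast
#' flicker arms remain realizable on either background.
#'
#' @param device A `device_model`.
#' @param sens A `receptor_sensitivities` on the device grid.
#' @param target_contrast Target Weber contrast of the directed mechanism
#'   between high and low (3.5 = the nominal 350% melanopic step).
#' @param direction `"Mel"` for a melanopsin-directed pair (cones silenced)
#'   or `"LMS"` for a cone-directed pair (melanopsin silenced); the latter is
#'   the Weber-law positive control.
#' @param cone_tolerance Acceptance tolerance on the silenced contrasts.
#' @param headroom Settings margin kept from 0 and 1 so flicker arms remain
#'   realizable (default 0.05 for a melanopsin-directed pair, 0.04 for the
#'   cone-directed control pair).
#' @param anchor Preferred (low, high) operating points in settings space.
#' @return List with `low_settings`, `high_settings`, `achieved_contrasts`
#'   (Weber contrasts of high vs low for all four receptors), `target`,
#'   `achieved_target`, and `feasible`.
#' @export
solve_background_pair <- function(device, sens, target_contrast = 3.5,
                                  direction = c("Mel", "LMS"),
                                  cone_tolerance = 1e-6, headroom = NULL,
                                  anchor = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(device, "device_model"))
  P <- device$n_primaries
  if (P < 4L) stop("silent substitution requires at least 4 primaries")
  rr <- receptor_rows(device, sens)

  directed <- if (direction == "Mel") "Mel" else c("L", "M", "S")
  silenced <- setdiff(RECEPTOR_LABELS, directed)
  if (is.null(anchor)) {
    anchor <- if (direction == "Mel") c(0.35, 0.65) else c(0.10, 0.70)
  }
  if (is.null(headroom)) headroom <- if (direction == "Mel") 0.05 else 0.04
  x0 <- c(rep(anchor[1], P), rep(anchor[2], P))
  lower <- rep(headroom, 2 * P)
  upper <- rep(1 - headroom, 2 * P)

  build <- function(target) {
    # silenced: r (s_hi - s_lo) = 0 ; directed: r s_hi - (1+T) r s_lo = T a_r
    A <- matrix(0, length(silenced) + length(directed), 2 * P)
    b <- numeric(nrow(A))
    i <- 0L
    for (r in silenced) {
      i <- i + 1L
      A[i, ] <- c(-rr$R[r, ], rr$R[r, ])
    }
    for (r in directed) {
      i <- i + 1L
      A[i, ] <- c(-(1 + target) * rr$R[r, ], rr$R[r, ])
      b[i] <- target * rr$ambient[[r]]
    }
    list(A = A, b = b)
  }
  try_target <- function(target) {
    ab <- build(target)
    solve_linear_design(ab$A, ab$b, x0, lower, upper)
  }

  x <- try_target(target_contrast)
  achieved_target <- target_contrast
  feasible <- !is.null(x)
  if (!feasible) {
    lo <- 0; hi <- target_contrast
    if (is.null(try_target(0))) {
      stop("background-pair design infeasible even at zero target contrast")
    }
    for (k in 1:40) {
      mid <- (lo + hi) / 2
      if (!is.null(try_target(mid))) lo <- mid else hi <- mid
    }
    achieved_target <- lo
    x <- try_target(lo)
    if (is.null(x) || achieved_target < 0.01) {
      stop(sprintf(
        "background-pair design infeasible at target %.3g; best achievable directed contrast ~ %.4g",
        target_contrast, achieved_target))
    }
    warning(sprintf(
      "target contrast %.3g infeasible within gamut; returning maximal achievable %.4g",
      target_contrast, achieved_target))
  }

  low <- x[1:P]; high <- x[(P + 1):(2 * P)]
  e_lo <- excitation(device_spectrum(device, low), sens)
  e_hi <- excitation(device_spectrum(device, high), sens)
  achieved <- weber_contrast(e_lo, e_hi)
  resid <- max(abs(achieved[silenced]))
  if (resid > cone_tolerance) {
    warning(sprintf("residual contrast on silenced mechanisms (%.3g) exceeds tolerance %.3g",
                    resid, cone_tolerance))
  }
  list(low_settings = low, high_settings = high,
       achieved_contrasts = achieved, target = target_contrast,
       achieved_target = achieved_target, direction = direction,
       feasible = feasible)
}

#' Design a cone-directed flicker modulation about a background
#'
#' Finds a settings deviation delta such that background + delta delivers
#' equal Weber contrast `lms_target` on each of the L, M and S cones while
#' leaving melanopsin excitation unchanged; the negative arm is the exact
#' mirror (background - delta). The least-norm deviation satisfying the four
#' linear excitation constraints is used.
#'
#' @inheritParams solve_background_pair
#' @param background_settings Settings of the adapting background.
#' @param lms_target Per-cone Weber contrast of the positive arm (0.05 = the
#'   nominal 5% maximum).
#' @param mel_tolerance Acceptance tolerance on the residual melanopsin
#'   contrast.
#' @param max_contrast Largest nominal contrast the modulation will be
#'   scaled to (default 0.05).
#' @param contrast_step Contrast grid step for scaling (default 0.001).
#' @return An object of class `modulation_spec`: background and arm settings,
#'   nominal contrast targets, the contrast grid (`max_contrast` 0.05,
#'   `contrast_step` 0.001) and achieved arm contrasts.
#' @export
solve_flicker_modulation <- function(device, sens, background_settings,
                                     lms_target = 0.05, mel_tolerance = 1e-6,
                                     max_contrast = 0.05,
                                     contrast_step = 0.001) {
  stopifnot(inherits(device, "device_model"))
  rr <- receptor_rows(device, sens)
  bg <- as.numeric(background_settings)
  e_bg <- excitation(device_spectrum(device, bg), sens)

  A <- rr$R[c("L", "M", "S", "Mel"), , drop = FALSE]
  b <- c(lms_target * e_bg[c("L", "M", "S")], 0)
  delta <- drop(crossprod(A, solve(tcrossprod(A), b)))

  # both arms must stay in gamut: |delta| <= min(bg, 1 - bg) componentwise
  room <- pmin(bg, 1 - bg)
  if (any(abs(delta) > room + 1e-9)) {
    delta <- solve_linear_design(A, b, numeric(length(bg)),
                                 lower = -room, upper = room)
    if (is.null(delta)) {
      ln <- drop(crossprod(A, solve(tcrossprod(A), b)))
      scale <- min(room / pmax(abs(ln), 1e-300))
      stop(sprintf(
        "flicker modulation at %.3g contrast leaves the gamut; achievable contrast ~ %.4g",
        lms_target, lms_target * max(0, scale)))
    }
  }
  pos <- pmin(1, pmax(0, bg + delta))
  neg <- pmin(1, pmax(0, bg - delta))

  e_pos <- excitation(device_spectrum(device, pos), sens)
  achieved <- weber_contrast(e_bg, e_pos)
  if (abs(achieved[["Mel"]]) > mel_tolerance) {
    warning(sprintf("residual melanopsin contrast %.3g exceeds tolerance %.3g",
                    achieved[["Mel"]], mel_tolerance))
  }
  structure(list(
    background_settings = bg, positive_arm_settings = pos,
    negative_arm_settings = neg,
    nominal_contrasts = c(L = lms_target, M = lms_target, S = lms_target, Mel = 0),
    max_contrast = max_contrast, contrast_step = contrast_step,
    achieved_contrasts = achieved),
    class = "modulation_spec")
}

#' @export
print.modulation_spec <- function(x, ...) {
  cat(sprintf("<modulation_spec> nominal LMS %.3g, max %.3g in %.3g steps; achieved L=%.4g M=%.4g S=%.4g Mel=%.3g\n",
              x$nominal_contrasts[["L"]], x$max_contrast, x$contrast_step,
              x$achieved_contrasts[["L"]], x$achieved_contrasts[["M"]],
              x$achieved_contrasts[["S"]], x$achieved_contrasts[["Mel"]]))
  invisible(x)
}

#' Snap a nominal contrast to the stimulus contrast grid
#'
#' Rounds to the nearest multiple of `step`, halves away from zero.
#'
#' @param contrast Nominal contrast value(s).
#' @param step Grid step (default 0.001 = 0.1% contrast).
#' @return Snapped contrast(s).
#' @export
snap_contrast <- function(contrast, step = 0.001) {
  sign(contrast) * floor(abs(contrast) / step + 0.5) * step
}

#' Scale a designed modulation to a nominal contrast
#'
#' The arm deviations from background scale by `nominal / max_contrast` after
#' snapping `nominal` to the contrast grid; nominal 0 returns the background
#' in both arms.
#'
#' @param spec A `modulation_spec`.
#' @param nominal_contrast Requested contrast in [0, max_contrast].
#' @param device Optional `device_model`; when given, rendered positive and
#'   negative arm spectra are included.
#' @return List with `scale`, `snapped_contrast`, `positive_settings`,
#'   `negative_settings`, and (with a device) `positive_spectrum`,
#'   `negative_spectrum`.
#' @export
scale_modulation <- function(spec, nominal_contrast, device = NULL) {
  stopifnot(inherits(spec, "modulation_spec"))
  if (nominal_contrast < 0 || nominal_contrast > spec$max_contrast + 1e-12) {
    stop(sprintf("nominal contrast %.4g outside [0, %g]",
                 nominal_contrast, spec$max_contrast))
  }
  snapped <- snap_contrast(nominal_contrast, spec$contrast_step)
  snapped <- min(snapped, spec$max_contrast)
  scale <- snapped / spec$max_contrast
  bg <- spec$background_settings
  pos <- bg + scale * (spec$positive_arm_settings - bg)
  neg <- bg + scale * (spec$negative_arm_settings - bg)
  out <- list(scale = scale, snapped_contrast = snapped,
              positive_settings = pos, negative_settings = neg)
  if (!is.null(device)) {
    out$positive_spectrum <- device_spectrum(device, pos)
    out$negative_spectrum <- device_spectrum(device, neg)
  }
  out
}

#' Re-solve a modulation accounting for a fixed scatter spectrum
#'
#' A steady scattered light adds to every stimulus and dilutes Weber
#' contrast. This re-solves the arm settings so that receptor contrasts
#' computed on the total light (device output + scatter) equal the nominal
#' targets.
#'
#' @inheritParams solve_flicker_modulation
#' @param spec The uncorrected `modulation_spec`.
#' @param scatter A `spectral_samples` scatter spectrum on the device grid.
#' @return A corrected `modulation_spec`.
#' @export
apply_scatter_correction <- function(spec, device, sens, scatter) {
  stopifnot(inherits(spec, "modulation_spec"))
  if (inherits(scatter, "spectral_samples")) {
    check_same_grid(device$wavelengths, scatter$wavelengths, "device", "scatter")
    sc <- scatter$power
  } else sc <- as.numeric(scatter)
  dev_total <- device_model(device$wavelengths, device$primaries,
                            quantization_levels = device$quantization_levels,
                            ambient = device$ambient + sc)
  solve_flicker_modulation(dev_total, sens, spec$background_settings,
                           lms_target = spec$nominal_contrasts[["L"]],
                           max_contrast = spec$max_contrast,
                           contrast_step = spec$contrast_step)
}

# ---- temporal waveforms -----------------------------------------------------

timeline_segment <- function(label, frame_rate, settings) {
  n <- nrow(settings)
  structure(list(label = label, frame_rate = frame_rate,
                 duration_ms = 1000 * n / frame_rate,
                 settings = settings),
            class = "timeline_segment")
}

#' Half-cosine pedestal ramp between two backgrounds
#'
#' Per-frame interpolation in settings space,
#' `w(t) = low + 0.5 * (1 - cos(pi t / T)) * (high - low)`, t in [0, T]:
#' starts exactly at the low settings and ends exactly at the high settings.
#'
#' @param low_settings,high_settings Endpoint settings vectors.
#' @param ramp_ms Ramp duration in ms (default 500).
#' @param frame_rate Frame rate in Hz (default 60).
#' @return A `timeline_segment` with one settings row per frame (the final
#'   frame lands on `high_settings`).
#' @export
pedestal_waveform <- function(low_settings, high_settings, ramp_ms = 500,
                              frame_rate = 60) {
  if (ramp_ms <= 0) stop("ramp duration must be positive")
  low <- as.numeric(low_settings); high <- as.numeric(high_settings)
  stopifnot(length(low) == length(high))
  n <- max(2L, round(ramp_ms / 1000 * frame_rate) + 1L)
  t <- seq(0, 1, length.out = n)
  w <- 0.5 * (1 - cos(pi * t))
  S <- outer(rep(1, n), low) + outer(w, high - low)
  timeline_segment("pedestal_ramp", frame_rate, S)
}

#' Sinusoidal flicker interval
#'
#' Frame f at time t carries background + sin(2 pi f_Hz t) times the scaled
#' arm deviation; the reference (no-flicker) interval uses the same frame
#' refresh with zero modulation so stimulus updating is identical in both
#' intervals.
#'
#' @param spec A `modulation_spec`.
#' @param nominal_contrast Contrast of the interval (snapped to the grid).
#' @param frequency_hz Flicker frequency (default 5 Hz).
#' @param duration_ms Interval duration (default 500 ms).
#' @param frame_rate Frame rate in Hz (default 60).
#' @return A `timeline_segment`.
#' @export
flicker_waveform <- function(spec, nominal_contrast, frequency_hz = 5,
                             duration_ms = 500, frame_rate = 60) {
  stopifnot(inherits(spec, "modulation_spec"))
  if (frequency_hz > frame_rate / 2) {
    stop(sprintf("flicker frequency %g Hz exceeds the Nyquist limit %g Hz of a %g Hz frame rate",
                 frequency_hz, frame_rate / 2, frame_rate))
  }
  sc <- scale_modulation(spec, nominal_contrast)
  n <- max(1L, round(duration_ms / 1000 * frame_rate))
  t <- (seq_len(n) - 1L) / frame_rate
  amp <- sin(2 * pi * frequency_hz * t)
  bg <- spec$background_settings
  dev <- sc$positive_settings - bg
  S <- outer(rep(1, n), bg) + outer(amp, dev)
  timeline_segment("flicker", frame_rate, S)
}

#' Assemble a 2IFC trial timeline
#'
#' Two 500 ms intervals separated by a 500 ms inter-stimulus interval; the
#' target interval carries the sinusoidal flicker, the other interval and the
#' ISI are reference segments refreshed at the same frame rate with zero
#' modulation.
#'
#' @inheritParams flicker_waveform
#' @param target_interval 1 or 2.
#' @return List of `timeline_segment`s with labels `interval1`, `isi`,
#'   `interval2` and an `interval_flags` attribute.
#' @export
trial_timeline <- function(spec, nominal_contrast, target_interval,
                           frequency_hz = 5, duration_ms = 500,
                           isi_ms = 500, frame_rate = 60) {
  stopifnot(target_interval %in% c(1L, 2L))
  flick <- function() flicker_waveform(spec, nominal_contrast, frequency_hz,
                                       duration_ms, frame_rate)
  ref <- function(ms) flicker_waveform(spec, 0, frequency_hz, ms, frame_rate)
  segs <- list(
    interval1 = if (target_interval == 1L) flick() else ref(duration_ms),
    isi = ref(isi_ms),
    interval2 = if (target_interval == 2L) flick() else ref(duration_ms))
  segs$interval1$label <- "interval1"
  segs$isi$label <- "isi"
  segs$interval2$label <- "interval2"
  attr(segs, "interval_flags") <- c(interval1 = target_interval == 1L,
                                    isi = FALSE,
                                    interval2 = target_interval == 2L)
  segs
}
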