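RECEPTOR_LABELS <- c("L", "M", "S", "Mel")

#' Default wavelength grid
#'
#' The standard sampling grid used throughout the package: 380-780 nm in
#' 2 nm steps (201 samples).
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
default_wavelengths <- function() seq(380, 780, by = 2)

check_uniform_grid <- function(wl, what = "wavelengths") {
  if (length(wl) < 2L) stop(what, " must contain at least two samples")
  d <- diff(wl)
  if (any(d <= 0)) stop(what, " must be strictly ascending")
  if (max(d) - min(d) > 1e-9) {
    stop(what, " must be a uniform grid (spacing varies by more than 1e-9 nm)")
  }
  invisible(d[1L])
}

check_same_grid <- function(wl_a, wl_b, name_a = "first", name_b = "second") {
  if (length(wl_a) != length(wl_b) || any(abs(wl_a - wl_b) > 1e-9)) {
    stop(sprintf(
      "wavelength grid mismatch: %s grid is [%g, %g] nm with %d samples; %s grid is [%g, %g] nm with %d samples",
      name_a, min(wl_a), max(wl_a), length(wl_a),
      name_b, min(wl_b), max(wl_b), length(wl_b)
    ))
  }
  invisible(TRUE)
}

#' Construct a spectral power distribution
#'
#' @param wavelengths Strictly ascending uniform wavelength grid in nm.
#' @param power Nonnegative spectral power, one value per wavelength, in
#'   arbitrary linear radiance units.
#' @return An object of class `spectral_samples`.
#' @export
spectral_samples <- function(wavelengths, power) {
  wavelengths <- as.numeric(wavelengths)
  power <- as.numeric(power)
  if (length(wavelengths) != length(power)) {
    stop("wavelengths and power must have the same length")
  }
  check_uniform_grid(wavelengths)
  if (any(power < 0)) stop("power must be nonnegative at every wavelength")
  structure(list(wavelengths = wavelengths, power = power),
            class = "spectral_samples")
}

#' @export
print.spectral_samples <- function(x, ...) {
  cat(sprintf("<spectral_samples> %d samples, %g-%g nm (step %g nm), total power %.4g\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              diff(x$wavelengths[1:2]), sum(x$power)))
  invisible(x)
}

#' Construct a photoreceptor spectral-sensitivity set
#'
#' Holds L-, M-, S-cone and melanopsin spectral sensitivities on a common
#' wavelength grid. Each curve is renormalized to a peak of exactly 1.
#' Field size, observer age and pupil diameter are carried as metadata; no
#' retinal-irradiance conversion is performed because all downstream analyses
#' work with Weber contrasts and normalized JNDs.
#'
#' @param wavelengths Uniform wavelength grid in nm.
#' @param curves Numeric matrix with one column per receptor, columns named
#'   `L`, `M`, `S`, `Mel`; nonnegative.
#' @param field_size Field size in degrees (metadata).
#' @param observer_age Observer age in years (metadata).
#' @param pupil_diameter Pupil diameter in mm (metadata).
#' @return An object of class `receptor_sensitivities`.
#' @export
receptor_sensitivities <- function(wavelengths, curves, field_size = 27.5,
                                   observer_age = 32, pupil_diameter = 6) {
  wavelengths <- as.numeric(wavelengths)
  check_uniform_grid(wavelengths)
  curves <- as.matrix(curves)
  if (!all(RECEPTOR_LABELS %in% colnames(curves))) {
    stop("curves must have columns named L, M, S, Mel")
  }
  curves <- curves[, RECEPTOR_LABELS, drop = FALSE]
  if (nrow(curves) != length(wavelengths)) {
    stop("curves must have one row per wavelength sample")
  }
  if (any(curves < 0)) stop("sensitivity curves must be nonnegative")
  peaks <- apply(curves, 2, max)
  if (any(peaks <= 0)) stop("each sensitivity curve must be positive somewhere")
  curves <- sweep(curves, 2, peaks, "/")
  structure(list(wavelengths = wavelengths, curves = curves,
                 field_size = field_size, observer_age = observer_age,
                 pupil_diameter = pupil_diameter),
            class = "receptor_sensitivities")
}

#' @export
print.receptor_sensitivities <- function(x, ...) {
  pk <- x$wavelengths[apply(x$curves, 2, which.max)]
  cat(sprintf("<receptor_sensitivities> peaks L=%g M=%g S=%g Mel=%g nm; field %g deg, age %g y, pupil %g mm\n",
              pk[1], pk[2], pk[3], pk[4], x$field_size, x$observer_age,
              x$pupil_diameter))
  invisible(x)
}

#' Physiologically shaped default sensitivity set
#'
#' A smooth synthetic stand-in for tabulated cone fundamentals and the
#' melanopsin spectral sensitivity: four unimodal Gaussian-shaped curves
#' peaking near 440 (S), 480 (Mel), 530 (M) and 560 (L) nm, each normalized
#' to a peak of 1. Real tabulated fundamentals can be supplied instead via
#' [read_sensitivities_csv()]; everything downstream only assumes curves on
#' a common grid with unit peaks.
#'
#' @param wavelengths Wavelength grid in nm.
#' @inheritParams receptor_sensitivities
#' @return A `receptor_sensitivities` object.
#' @export
default_sensitivities <- function(wavelengths = default_wavelengths(),
                                  field_size = 27.5, observer_age = 32,
                                  pupil_diameter = 6) {
  peaks <- c(L = 560, M = 530, S = 440, Mel = 480)
  sds <- c(L = 32, M = 30, S = 20, Mel = 28)
  curves <- sapply(RECEPTOR_LABELS, function(r) {
    exp(-0.5 * ((wavelengths - peaks[[r]]) / sds[[r]])^2)
  })
  receptor_sensitivities(wavelengths, curves, field_size = field_size,
                         observer_age = observer_age,
                         pupil_diameter = pupil_diameter)
}

#' Synthetic lens optical-density template
#'
#' A smooth synthetic template for human crystalline-lens optical density:
#' high absorbance at short wavelengths decaying to ~0 above ~550 nm. The
#' density scales with age relative to a reference age of 32 years, so that
#' older observers lose relative short-wavelength sensitivity. This is a
#' synthetic, physiologically shaped stand-in, not a tabulated standard.
#'
#' @param wavelengths Wavelength grid in nm.
#' @param age Observer age in years; valid range 20-80.
#' @param reference_age Age at which the template density applies unscaled.
#' @return List with `wavelengths`, `density` (decadic OD) and
#'   `transmittance` (`10^-density`).
#' @export
lens_density_template <- function(wavelengths = default_wavelengths(),
                                  age = 32, reference_age = 32) {
  if (age < 20 || age > 80) {
    stop("observer age ", age, " outside the supported range [20, 80] years")
  }
  base <- 1.2 * exp(-(wavelengths - 380) / 45)
  scale <- 1 + 0.02 * (age - reference_age)
  density <- base * scale
  list(wavelengths = wavelengths, density = density,
       transmittance = 10^(-density))
}

#' Apply age-predicted lens filtering to a sensitivity set
#'
#' Multiplies each receptor sensitivity by the age-scaled lens transmittance
#' and renormalizes each curve to a peak of 1, mirroring how stimuli are
#' tailored to the age-predicted pre-receptoral filtering of an observer.
#'
#' @param sens A `receptor_sensitivities` object.
#' @param observer_age Age in years, within [20, 80].
#' @param template Optional lens template as from [lens_density_template()];
#'   by default the packaged synthetic template at `observer_age`.
#' @return A new `receptor_sensitivities` object with updated metadata.
#' @export
lens_adjusted_sensitivities <- function(sens, observer_age, template = NULL) {
  stopifnot(inherits(sens, "receptor_sensitivities"))
  if (is.null(template)) {
    template <- lens_density_template(sens$wavelengths, age = observer_age)
  }
  check_same_grid(sens$wavelengths, template$wavelengths,
                  "sensitivity", "lens template")
  curves <- sens$curves * template$transmittance
  receptor_sensitivities(sens$wavelengths, curves,
                         field_size = sens$field_size,
                         observer_age = observer_age,
                         pupil_diameter = sens$pupil_diameter)
}

#' Photoreceptor excitations from a spectrum
#'
#' Rectangle-rule integral of spectrum times sensitivity:
#' `e_r = sum_lambda S_r(lambda) * Phi(lambda) * dlambda` for each receptor
#' class r in L, M, S, Mel. Exactly linear in the input spectrum.
#'
#' @param spd A `spectral_samples` object (or a bare power vector on the
#'   sensitivity grid).
#' @param sens A `receptor_sensitivities` object.
#' @return Named numeric vector of excitations (power units x nm) for
#'   L, M, S, Mel.
#' @export
excitation <- function(spd, sens) {
  stopifnot(inherits(sens, "receptor_sensitivities"))
  if (inherits(spd, "spectral_samples")) {
    check_same_grid(spd$wavelengths, sens$wavelengths, "spectrum", "sensitivity")
    power <- spd$power
  } else {
    power <- as.numeric(spd)
    if (length(power) != length(sens$wavelengths)) {
      stop("power vector length does not match the sensitivity grid")
    }
  }
  dl <- sens$wavelengths[2L] - sens$wavelengths[1L]
  drop(crossprod(sens$curves, power)) * dl
}

#' Per-receptor Weber contrast between two excitation vectors
#'
#' `c_r = (e_mod,r - e_bg,r) / e_bg,r` per receptor label.
#'
#' @param background,modulated Named excitation vectors as from [excitation()].
#' @return Named numeric vector of signed Weber contrasts.
#' @export
weber_contrast <- function(background, modulated) {
  labs <- intersect(RECEPTOR_LABELS, intersect(names(background), names(modulated)))
  if (!length(labs)) stop("no shared receptor labels between the two excitation vectors")
  bg <- background[labs]
  if (any(bg <= 0)) {
    stop("Weber contrast undefined: zero or negative background excitation for ",
         paste(labs[bg <= 0], collapse = ", "))
  }
  (modulated[labs] - bg) / bg
}

#' Combined LMS content of an excitation vector
#'
#' The unweighted mean of the L-, M- and S-cone excitations. The mean (rather
#' than sum) convention is adopted throughout; the two differ by a constant
#' factor of 3 that cancels in every contrast and in all normalized JND
#' statistics.
#'
#' @param exc Named excitation vector containing L, M, S.
#' @param convention `"mean"` (default) or `"sum"`; provided so the
#'   factor-of-three invariance can be demonstrated.
#' @return Scalar LMS content.
#' @export
lms_content <- function(exc, convention = c("mean", "sum")) {
  convention <- match.arg(convention)
  v <- exc[c("L", "M", "S")]
  if (anyNA(v)) stop("excitation vector must contain L, M and S")
  if (convention == "mean") mean(v) else sum(v)
}

#' Combined LMS Weber contrast
#'
#' Equally weighted combination (mean) of the three cone Weber contrasts, so
#' that a modulation delivering 5% contrast on each cone class has an LMS
#' contrast of exactly 0.05.
#'
#' @inheritParams weber_contrast
#' @return Scalar signed LMS contrast.
#' @export
lms_contrast <- function(background, modulated) {
  cc <- weber_contrast(background, modulated)
  mean(cc[c("L", "M", "S")])
}

#' Chromatic splatter ratio (L - M) / (L + M + S)
#'
#' The L-minus-M cone contrast expressed relative to the combined LMS
#' contrast of the same modulation. Invariant to uniform scaling of the
#' modulation arm and to the mean-vs-sum LMS convention.
#'
#' @inheritParams weber_contrast
#' @return Scalar signed ratio.
#' @export
lm_over_lms <- function(background, modulated) {
  cc <- weber_contrast(background, modulated)
  lms <- mean(cc[c("L", "M", "S")])
  if (lms == 0) stop("LMS contrast is zero; (L-M)/LMS ratio undefined")
  (cc[["L"]] - cc[["M"]]) / lms
}

# ---- CSV interfaces ---------------------------------------------------------

#' Read / write spectra and sensitivities as CSV
#'
#' Spectrum CSV: columns `wavelength_nm`, `power`. Sensitivity CSV: columns
#' `wavelength_nm`, `L`, `M`, `S`, `Mel`. Header row required, UTF-8,
#' decimal point.
#'
#' @param path File path.
#' @name spectra_csv
NULL

#' @rdname spectra_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path, check.names = TRUE)
  if (!all(c("wavelength_nm", "power") %in% names(d))) {
    stop("spectrum CSV must have columns wavelength_nm, power: ", path)
  }
  spectral_samples(d$wavelength_nm, d$power)
}

#' @rdname spectra_csv
#' @param spd A `spectral_samples` object.
#' @export
write_spectrum_csv <- function(spd, path) {
  utils::write.csv(
    data.frame(wavelength_nm = spd$wavelengths, power = spd$power),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname spectra_csv
#' @inheritParams receptor_sensitivities
#' @export
read_sensitivities_csv <- function(path, field_size = 27.5, observer_age = 32,
                                   pupil_diameter = 6) {
  d <- utils::read.csv(path, check.names = TRUE)
  need <- c("wavelength_nm", RECEPTOR_LABELS)
  if (!all(need %in% names(d))) {
    stop("sensitivity CSV must have columns wavelength_nm, L, M, S, Mel: ", path)
  }
  receptor_sensitivities(d$wavelength_nm, as.matrix(d[RECEPTOR_LABELS]),
                         field_size = field_size, observer_age = observer_age,
                         pupil_diameter = pupil_diameter)
}

#' @rdname spectra_csv
#' @param sens A `receptor_sensitivities` object.
#' @export
write_sensitivities_csv <- function(sens, path) {
  d <- data.frame(wavelength_nm = sens$wavelengths, sens$curves)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
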