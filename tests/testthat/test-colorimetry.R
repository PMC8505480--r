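test_that("excitation is the rectangle-rule integral and is exactly linear", {
  # flat spectrum of 1 on an 11-point grid with step 10 nm, unit sensitivity:
  # sum of 11 samples x 10 nm = 110
  flat <- spectral_samples(toy_grid, rep(1, 11))
  e <- excitation(flat, toy_sens_flat)
  expect_equal(unname(e), rep(110, 4))

  zero <- spectral_samples(toy_grid, rep(0, 11))
  expect_equal(unname(excitation(zero, toy_sens_flat)), rep(0, 4))

  set.seed(42)
  for (i in 1:5) {
    p1 <- spectral_samples(toy_grid, runif(11))
    p2 <- spectral_samples(toy_grid, runif(11))
    a <- runif(1, 0, 3); b <- runif(1, 0, 3)
    mix <- spectral_samples(toy_grid, a * p1$power + b * p2$power)
    expect_equal(excitation(mix, toy_sens_flat),
                 a * excitation(p1, toy_sens_flat) +
                   b * excitation(p2, toy_sens_flat))
  }
  doubled <- spectral_samples(toy_grid, 2 * flat$power)
  expect_equal(excitation(doubled, toy_sens_flat),
               2 * excitation(flat, toy_sens_flat))
})

test_that("grid mismatches are rejected with both grids named", {
  other <- spectral_samples(seq(400, 500, by = 5), rep(1, 21))
  expect_error(excitation(other, toy_sens_flat), "mismatch.*21 samples",
               ignore.case = TRUE)
  expect_error(spectral_samples(c(400, 410, 425), c(1, 1, 1)), "uniform")
  expect_error(spectral_samples(toy_grid, rep(-1, 11)), "nonnegative")
})

test_that("Weber contrast has the standard sign convention and zero fixed point", {
  bg <- exc_vec(1, 1, 1, 1)
  expect_equal(weber_contrast(bg, exc_vec(1, 1, 1, 4.5))[["Mel"]], 3.5)
  expect_equal(unname(weber_contrast(bg, bg)), rep(0, 4))
  expect_equal(weber_contrast(exc_vec(2, 2, 2, 2), exc_vec(1, 1, 1, 1))[["L"]],
               -0.5)
  # invariant to common scaling of both spectra
  mod <- exc_vec(1.2, 0.9, 1.1, 2)
  expect_equal(weber_contrast(7 * bg, 7 * mod), weber_contrast(bg, mod))
  expect_error(weber_contrast(exc_vec(0, 1, 1, 1), bg), "zero or negative")
})

test_that("LMS content and contrast use the equally weighted mean", {
  expect_equal(lms_content(exc_vec(5, 5, 5)), 5)
  expect_equal(lms_content(exc_vec(1, 2, 3)), 2)
  expect_equal(lms_content(exc_vec(1, 2, 3), convention = "sum"), 6)
  expect_equal(lms_content(exc_vec(3, 6, 9)), 3 * lms_content(exc_vec(1, 2, 3)))

  bg <- exc_vec(1, 1, 1)
  expect_equal(lms_contrast(bg, exc_vec(1.05, 1.05, 1.05)), 0.05)
  expect_equal(lms_contrast(bg, exc_vec(1.05, 0.95, 1)), 0)
  expect_equal(lms_contrast(bg, exc_vec(1.03, 1.04, 1.05)), 0.04)
})

test_that("(L-M)/LMS ratio matches hand arithmetic and is scale invariant", {
  bg <- exc_vec(1, 1, 1)
  mod <- exc_vec(1.055, 1.050, 1.045)
  expect_equal(lm_over_lms(bg, mod), (0.055 - 0.050) / 0.05)
  expect_equal(lm_over_lms(bg, exc_vec(1.05, 1.05, 1.02)), 0)
  # homogeneity of degree 0 in the modulation-arm deviation
  k <- 0.37
  scaled <- bg + k * (mod - bg)
  expect_equal(lm_over_lms(bg, scaled), lm_over_lms(bg, mod))
  expect_error(lm_over_lms(bg, exc_vec(1.05, 0.95, 1)), "zero")
})

test_that("lens adjustment renormalizes, preserves the reference age, and dims blue with age", {
  s0 <- default_sensitivities()
  ref <- lens_adjusted_sensitivities(s0, observer_age = 32)
  adj32 <- lens_adjusted_sensitivities(s0, observer_age = 32)
  expect_equal(adj32$curves, ref$curves)
  expect_equal(unname(apply(ref$curves, 2, max)), rep(1, 4))

  # identity template leaves curves untouched
  ident <- list(wavelengths = s0$wavelengths,
                transmittance = rep(1, length(s0$wavelengths)))
  expect_equal(lens_adjusted_sensitivities(s0, 32, template = ident)$curves,
               s0$curves)

  # relative short-wavelength sensitivity is non-increasing in age
  ratio_at <- function(sens, wl) {
    i420 <- which.min(abs(sens$wavelengths - 420))
    i560 <- which.min(abs(sens$wavelengths - 560))
    sens$curves[i420, "S"] / max(sens$curves[i560, "S"], 1e-12)
  }
  ages <- c(20, 30, 40, 55, 70, 80)
  ratios <- sapply(ages, function(a) ratio_at(lens_adjusted_sensitivities(s0, a), a))
  expect_true(all(diff(ratios) <= 1e-12))

  expect_error(lens_adjusted_sensitivities(s0, 95), "range")
  expect_error(lens_adjusted_sensitivities(s0, 10), "range")
})

test_that("sensitivity curves are normalized to unit peak on construction", {
  wl <- default_wavelengths()
  raw <- sapply(c(560, 530, 440, 480), function(p) 3 * exp(-((wl - p) / 40)^2))
  colnames(raw) <- c("L", "M", "S", "Mel")
  s <- receptor_sensitivities(wl, raw)
  expect_equal(unname(apply(s$curves, 2, max)), rep(1, 4))
})

test_that("spectrum and sensitivity CSVs round-trip", {
  spd <- spectral_samples(toy_grid, seq(0, 1, length.out = 11))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(spd, f)
  expect_equal(read_spectrum_csv(f)$power, spd$power)

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_sensitivities_csv(fx$sens, f2)
  back <- read_sensitivities_csv(f2)
  expect_equal(back$curves, fx$sens$curves, tolerance = 1e-12)
})
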