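test_that("the melanopsin-directed background pair hits 350% contrast with silent cones", {
  pair <- fx$pair
  expect_true(pair$feasible)
  expect_equal(pair$achieved_contrasts[["Mel"]], 3.5, tolerance = 1e-9)
  expect_lt(max(abs(pair$achieved_contrasts[c("L", "M", "S")])), 1e-6)
  # 350% Weber contrast is exactly a 4.5x excitation ratio
  e_lo <- excitation(device_spectrum(fx$device, pair$low_settings), fx$sens)
  e_hi <- excitation(device_spectrum(fx$device, pair$high_settings), fx$sens)
  expect_equal(e_hi[["Mel"]] / e_lo[["Mel"]], 4.5, tolerance = 1e-9)
  # headroom: both backgrounds admit the +/-5% flicker arms (solved in fx)
  expect_true(all(fx$spec_low$positive_arm_settings >= 0 &
                    fx$spec_low$positive_arm_settings <= 1))
  expect_true(all(fx$spec_high$negative_arm_settings >= 0 &
                    fx$spec_high$negative_arm_settings <= 1))
})

test_that("a zero-contrast target is satisfied with all mechanisms silent", {
  pair0 <- solve_background_pair(fx$device, fx$sens, target_contrast = 0)
  expect_lt(max(abs(pair0$achieved_contrasts)), 1e-6)
})

test_that("the solver's maximal melanopic contrast matches a brute-force grid search", {
  # 4-primary toy device where the 350% target is out of gamut: the solver
  # bisects to the maximal achievable contrast, which must not be beaten by
  # an exhaustive 0.05-resolution search over the high settings
  sens <- fx$sens
  toy <- make_synthetic_device(n_primaries = 4, peak_range_nm = c(430, 620),
                               bandwidth_nm = 25, seed = 3)
  sol <- suppressWarnings(solve_background_pair(toy, sens, 3.5))
  expect_false(sol$feasible)
  expect_lt(max(abs(sol$achieved_contrasts[c("L", "M", "S")])), 1e-6)

  e_lo <- excitation(device_spectrum(toy, sol$low_settings), sens)
  grid1 <- seq(0.05, 0.95, by = 0.05)
  S <- t(as.matrix(expand.grid(grid1, grid1, grid1, grid1)))
  dl <- diff(toy$wavelengths[1:2])
  E <- (crossprod(sens$curves, toy$primaries) * dl) %*% S +
    excitation(toy$ambient, sens)
  cones_ok <- apply(abs(E[c("L", "M", "S"), ] / e_lo[c("L", "M", "S")] - 1),
                    2, max) <= 0.02
  grid_best <- max(E["Mel", cones_ok] / e_lo[["Mel"]] - 1)
  expect_gte(sol$achieved_target, grid_best - 0.05)
})

test_that("flicker modulations deliver 5% on each cone with melanopsin silent", {
  for (spec in list(fx$spec_low, fx$spec_high)) {
    expect_equal(unname(spec$achieved_contrasts[c("L", "M", "S")]),
                 rep(0.05, 3), tolerance = 1e-6)
    expect_lt(abs(spec$achieved_contrasts[["Mel"]]), 1e-6)
  }
  # zero-contrast target: both arms equal the background
  spec0 <- solve_flicker_modulation(fx$device, fx$sens,
                                    fx$pair$low_settings, lms_target = 0)
  expect_equal(spec0$positive_arm_settings, spec0$background_settings,
               tolerance = 1e-9)
})

test_that("the designed arm solves the linearized excitation constraints (linear-algebra oracle)", {
  # independent construction: stack the four excitation constraint rows and
  # solve by least-norm QR; the designed deviation must satisfy A d = b
  dev <- fx$device; sens <- fx$sens
  bg <- fx$pair$low_settings
  dl <- diff(dev$wavelengths[1:2])
  R <- crossprod(sens$curves, dev$primaries) * dl
  e_bg <- excitation(device_spectrum(dev, bg), sens)
  A <- R[c("L", "M", "S", "Mel"), ]
  b <- c(0.05 * e_bg[c("L", "M", "S")], 0)
  sv <- svd(A)
  d_oracle <- drop(sv$v %*% (crossprod(sv$u, b) / sv$d))  # SVD pseudoinverse
  d_pkg <- fx$spec_low$positive_arm_settings - bg
  expect_equal(drop(A %*% d_pkg), b, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(d_pkg, d_oracle, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("contrast scaling snaps to the 0.1% grid and scales deviations", {
  spec <- fx$spec_low
  bg <- spec$background_settings
  full <- scale_modulation(spec, 0.05)
  expect_equal(full$scale, 1)
  expect_equal(full$positive_settings, spec$positive_arm_settings)

  zero <- scale_modulation(spec, 0)
  expect_equal(zero$positive_settings, bg)
  expect_equal(zero$negative_settings, bg)

  sc <- scale_modulation(spec, 0.0234)
  expect_equal(sc$snapped_contrast, 0.023)
  expect_equal(sc$scale, 0.46)
  expect_equal(sc$positive_settings - bg,
               0.46 * (spec$positive_arm_settings - bg))

  expect_error(scale_modulation(spec, -0.01), "outside")
  expect_error(scale_modulation(spec, 0.06), "outside")
  # half-away-from-zero rounding on the grid
  expect_equal(snap_contrast(0.0025), 0.003)
  expect_equal(snap_contrast(-0.0025), -0.003)
})

test_that("scatter correction restores nominal contrast on the total light", {
  dev <- fx$device; sens <- fx$sens
  spec <- fx$spec_low
  bg_spd <- device_spectrum(dev, spec$background_settings)

  # zero scatter: nothing changes
  same <- apply_scatter_correction(spec, dev, sens,
                                   spectral_samples(dev$wavelengths,
                                                    rep(0, length(dev$wavelengths))))
  expect_equal(same$positive_arm_settings, spec$positive_arm_settings,
               tolerance = 1e-9)

  # scatter equal to the background halves the uncorrected Weber contrast
  e_bg <- excitation(bg_spd, sens)
  e_pos <- excitation(device_spectrum(dev, spec$positive_arm_settings), sens)
  e_sc <- e_bg  # scatter == background spectrum
  uncorrected <- lms_contrast(e_bg + e_sc, e_pos + e_sc)
  expect_equal(uncorrected, 0.05 / 2, tolerance = 1e-9)

  # corrected arms restore the nominal contrast on the total light
  corr <- apply_scatter_correction(spec, dev, sens, bg_spd)
  tot_bg <- excitation(device_spectrum(dev, corr$background_settings), sens) + e_sc
  tot_pos <- excitation(device_spectrum(dev, corr$positive_arm_settings), sens) + e_sc
  expect_equal(unname(weber_contrast(tot_bg, tot_pos)[c("L", "M", "S")]),
               rep(0.05, 3), tolerance = 1e-6)
})

test_that("the pedestal ramp is a half-cosine in settings space with monotone melanopic rise", {
  lo <- fx$pair$low_settings; hi <- fx$pair$high_settings
  seg <- pedestal_waveform(lo, hi, ramp_ms = 500, frame_rate = 60)
  n <- nrow(seg$settings)
  expect_equal(seg$settings[1, ], lo, ignore_attr = TRUE)
  expect_equal(seg$settings[n, ], hi, ignore_attr = TRUE)
  mid <- seg$settings[(n + 1) / 2, ]  # odd frame count: exact midpoint frame
  expect_equal(mid, (lo + hi) / 2, tolerance = 1e-9, ignore_attr = TRUE)

  mel <- apply(seg$settings, 1, function(s)
    excitation(device_spectrum(fx$device, s), fx$sens)[["Mel"]])
  expect_true(all(diff(mel) >= -1e-12))
  expect_error(pedestal_waveform(lo, hi, ramp_ms = 0), "positive")
})

test_that("the flicker waveform runs 2.5 sinusoidal cycles and peaks at the positive arm", {
  spec <- fx$spec_low
  seg <- flicker_waveform(spec, 0.05, frequency_hz = 5, duration_ms = 500,
                          frame_rate = 60)
  expect_equal(nrow(seg$settings), 30)
  # projection onto the arm deviation reproduces sin(2 pi 5 t) exactly
  dirn <- spec$positive_arm_settings - spec$background_settings
  amp <- drop((seg$settings - outer(rep(1, 30), spec$background_settings)) %*%
                dirn) / sum(dirn^2)
  t <- (0:29) / 60
  expect_equal(amp, sin(2 * pi * 5 * t), tolerance = 1e-9)

  # frame 4 (t = 0.05 s) is the quarter-cycle peak: excitation equals the arm
  e_frame <- excitation(device_spectrum(fx$device, seg$settings[4, ]), fx$sens)
  e_arm <- excitation(device_spectrum(fx$device, spec$positive_arm_settings),
                      fx$sens)
  expect_equal(e_frame, e_arm, tolerance = 1e-9)

  still <- flicker_waveform(spec, 0, frame_rate = 60)
  expect_equal(max(abs(sweep(still$settings, 2, spec$background_settings))), 0)
  expect_error(flicker_waveform(spec, 0.05, frequency_hz = 40, frame_rate = 60),
               "Nyquist")
})

test_that("trial timelines put the flicker in the target interval only", {
  tl <- trial_timeline(fx$spec_low, 0.03, target_interval = 2)
  flags <- attr(tl, "interval_flags")
  expect_false(flags[["interval1"]]); expect_true(flags[["interval2"]])
  bg <- fx$spec_low$background_settings
  expect_equal(max(abs(sweep(tl$interval1$settings, 2, bg))), 0)
  expect_gt(max(abs(sweep(tl$interval2$settings, 2, bg))), 0)
  # gamut safety across every frame of every segment
  for (seg in tl) expect_true(all(seg$settings >= 0 & seg$settings <= 1))
})

test_that("8-bit settings quantization perturbs achieved contrasts by a bounded amount", {
  dev <- fx$device; sens <- fx$sens
  q <- function(s) quantize_settings(s, 256)
  e_bg <- excitation(device_spectrum(dev, q(fx$spec_low$background_settings)), sens)
  e_pos <- excitation(device_spectrum(dev, q(fx$spec_low$positive_arm_settings)), sens)
  cc <- weber_contrast(e_bg, e_pos)
  expect_lt(max(abs(cc[c("L", "M", "S")] - 0.05)), 0.02)
  expect_lt(abs(cc[["Mel"]]), 0.05)

  e_lo <- excitation(device_spectrum(dev, q(fx$pair$low_settings)), sens)
  e_hi <- excitation(device_spectrum(dev, q(fx$pair$high_settings)), sens)
  cb <- weber_contrast(e_lo, e_hi)
  expect_lt(abs(cb[["Mel"]] - 3.5), 0.1)
  expect_lt(max(abs(cb[c("L", "M", "S")])), 0.01)
  # quantization levels are respected
  expect_true(all(abs(q(fx$pair$low_settings) * 255 -
                        round(q(fx$pair$low_settings) * 255)) < 1e-9))
})
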