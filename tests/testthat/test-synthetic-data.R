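test_that("synthetic devices satisfy the device invariants and are seed-deterministic", {
  dev <- make_synthetic_device(n_primaries = 8, seed = 5)
  expect_s3_class(dev, "device_model")
  expect_equal(dev$n_primaries, 8)
  expect_true(all(dev$primaries >= 0))
  dev2 <- make_synthetic_device(n_primaries = 8, seed = 5)
  expect_identical(dev$primaries, dev2$primaries)
  dev3 <- make_synthetic_device(n_primaries = 8, seed = 6)
  expect_false(identical(dev$primaries, dev3$primaries))
  expect_error(make_synthetic_device(n_primaries = 2), "at least 3")
  expect_error(make_synthetic_device(peak_range_nm = c(300, 700)), "inside")
  # the default device supports the full 350% melanopic design
  expect_true(fx$pair$feasible)
})

test_that("device perturbation is identity at zero spread and produces measurable splatter", {
  dev <- fx$device
  same <- perturb_device(dev, gain_sd = 0, peak_shift_sd_nm = 0, seed = 3)
  expect_equal(same$primaries, dev$primaries, tolerance = 1e-12)

  p1 <- perturb_device(dev, 0.01, 1, seed = 3)
  p2 <- perturb_device(dev, 0.01, 1, seed = 3)
  expect_identical(p1$primaries, p2$primaries)

  # nominal cone-silent backgrounds acquire nonzero measured cone contrast
  e_lo <- excitation(device_spectrum(p1, fx$pair$low_settings), fx$sens)
  e_hi <- excitation(device_spectrum(p1, fx$pair$high_settings), fx$sens)
  splat <- weber_contrast(e_lo, e_hi)[c("L", "M", "S")]
  expect_gt(max(abs(splat)), 1e-4)
  expect_lt(max(abs(splat)), 0.2)
})

test_that("simulated observers respect the Weibull with a 50% guess floor", {
  obs <- observer_model(alpha = 0.013, beta = 3, lambda = 0)
  set.seed(77)
  # zero contrast: performance at the guess rate
  hits0 <- replicate(20000, observer_response(obs, 0, 1L)$correct)
  expect_equal(mean(hits0), 0.5, tolerance = 0.015)
  # at c = alpha: closed form 0.5 + 0.5 * (1 - exp(-1)) ~ 0.816
  hits_a <- replicate(20000, observer_response(obs, 0.013, 2L)$correct)
  expect_equal(mean(hits_a), 0.5 + 0.5 * (1 - exp(-1)), tolerance = 0.015)
  # saturation far above threshold
  expect_equal(observer_prob(obs, 1), 1, tolerance = 1e-6)
  # the response interval is the target iff correct
  r <- observer_response(obs, 0.05, 2L)
  expect_equal(r$response_interval, if (r$correct) 2L else 1L)
})

test_that("the condition effect scales the high-condition threshold", {
  obs <- observer_model(alpha = 0.013, condition_effect = 4.5)
  expect_equal(observer_prob(obs, 0.013 * 4.5, "high"),
               observer_prob(obs, 0.013, "low"))
})

test_that("sessions run 120 trials per condition, 40 per staircase, and splatter feeds behavior", {
  ses <- generate_session(fx$designs, observer_model(), fx$sens, seed = 12)
  tr <- ses$trials
  expect_equal(nrow(tr), 240)
  expect_equal(unname(table(tr$condition)), rep(120L, 2), ignore_attr = TRUE)
  expect_equal(unname(table(tr$condition, tr$staircase_id)),
               matrix(40L, 2, 3), ignore_attr = TRUE)
  expect_named(ses$measurements, c("low", "high"))
  # unperturbed device: measured flicker ratio is 1
  expect_equal(ses$measurements$low$flicker_ratio, 1, tolerance = 1e-6)
})

test_that("a full study has the expected size, determinism, and a lossless trial log", {
  sc <- study_config(n_participants = 3, n_sessions = 4, seed = 2)
  st <- generate_study(sc, fx$designs, fx$sens)
  expect_equal(nrow(st$trials), 3 * 4 * 2 * 120)
  expect_equal(length(st$sessions), 12)

  st2 <- generate_study(sc, fx$designs, fx$sens)
  expect_identical(st$trials, st2$trials)

  # distinct participants see distinct trial sequences
  t1 <- st$trials[st$trials$participant == 1 & st$trials$session == 1, ]
  t2 <- st$trials[st$trials$participant == 2 & st$trials$session == 1, ]
  expect_false(identical(t1$nominal_contrast, t2$nominal_contrast))

  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(st$trials, f, experiment = "exp1")
  back <- read_trial_log(f)
  expect_equal(nrow(back), nrow(st$trials))
  expect_equal(back$nominal_contrast, st$trials$nominal_contrast)
  expect_equal(back$correct, st$trials$correct)
})

test_that("a Weber-sized condition effect is recovered by the fitting pipeline", {
  sc <- study_config(n_participants = 1, n_sessions = 4, seed = 3)
  st <- generate_study(sc, fx$designs, fx$sens,
                       observers = list(observer_model(condition_effect = 4.5)))
  ft <- fit_thresholds_study(st)
  hi <- ft$results$normalized_jnd[ft$results$condition == "high"]
  expect_equal(median(hi), 4.5, tolerance = 0.3)
  expect_true(all(ft$differences$difference > 0))
})

test_that("null studies are unbiased and the median CI attains its intrinsic small-n coverage", {
  # the notch-style CI (median +/- 1.58 IQR / sqrt(n)) is anti-conservative
  # at n = 4; the pipeline should introduce no bias and no excess
  # anticoverage beyond the interval's own small-n behavior, which is
  # computed here as an iid-normal reference oracle
  set.seed(404)
  ref <- mean(replicate(4000, {
    x <- rnorm(4)
    hw <- 1.58 * IQR(x) / 2
    abs(median(x)) <= hw
  }))
  meds <- numeric(60); cover <- logical(60)
  for (r in 1:60) {
    sc <- study_config(n_participants = 1, n_sessions = 4, seed = 4000 + r)
    st <- generate_study(sc, fx$designs, fx$sens)
    ft <- fit_thresholds_study(st)
    meds[r] <- ft$summaries$median_diff
    cover[r] <- ft$summaries$covers_zero
  }
  expect_lt(abs(median(meds)), 0.1)          # no systematic condition effect
  expect_lt(abs(mean(cover) - ref), 0.15)    # coverage at the intrinsic rate
})
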