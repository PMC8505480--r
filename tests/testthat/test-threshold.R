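test_that("the Weibull ML fit recovers generating parameters from staircase data", {
  obs <- observer_model(alpha = 0.013, beta = 3, lambda = 0.01)
  cb <- function(contrast, ti) observer_response(obs, contrast, ti)
  recs <- do.call(rbind, lapply(1:4, function(s) run_block(cb, seed = 700 + s)))
  fit <- fit_weibull(recs)
  expect_lt(abs(fit$alpha / 0.013 - 1), 0.15)
  expect_equal(predict_fit(fit, 0), 0.5)  # guess rate pins p(0)
  expect_true(fit$lambda >= 0 && fit$lambda <= 0.05)
})

test_that("the ML optimum beats an exhaustive 11x11x6 likelihood grid", {
  set.seed(9)
  contrasts <- seq(0.002, 0.05, length.out = 8)
  p_true <- weibull_prob(contrasts, 0.015, 2.5, 0.5, 0.02)
  agg <- data.frame(contrast = contrasts,
                    n_correct = rbinom(8, 40, p_true), n_total = 40)
  fit <- fit_weibull(agg)
  nll <- function(a, b, l) {
    p <- pmin(pmax(weibull_prob(agg$contrast, a, b, 0.5, l), 1e-12), 1 - 1e-12)
    -sum(agg$n_correct * log(p) + (agg$n_total - agg$n_correct) * log(1 - p))
  }
  grid <- expand.grid(a = exp(seq(log(0.002), log(0.1), length.out = 11)),
                      b = exp(seq(log(0.3), log(15), length.out = 11)),
                      l = seq(0, 0.05, length.out = 6))
  grid_best <- min(mapply(nll, grid$a, grid$b, grid$l))
  expect_lte(fit$neg_log_likelihood, grid_best + 1e-6)
})

test_that("adding multistart points never worsens the best likelihood", {
  set.seed(11)
  contrasts <- seq(0.002, 0.05, length.out = 8)
  agg <- data.frame(contrast = contrasts,
                    n_correct = rbinom(8, 30, weibull_prob(contrasts, 0.012, 3)),
                    n_total = 30)
  f1 <- fit_weibull(agg, n_starts = 1)
  f5 <- fit_weibull(agg, n_starts = 5)
  expect_lte(f5$neg_log_likelihood, f1$neg_log_likelihood + 1e-9)
})

test_that("degenerate response data are rejected", {
  allc <- data.frame(nominal_contrast = rep(c(0.01, 0.02), 10),
                     correct = TRUE)
  expect_error(fit_weibull(allc), "degenerate")
  allw <- data.frame(nominal_contrast = rep(c(0.01, 0.02), 10),
                     correct = FALSE)
  expect_error(fit_weibull(allw), "degenerate")
})

test_that("threshold inversion matches the closed form and a root-finding oracle", {
  fit <- structure(list(alpha = 0.02, beta = 1, gamma = 0.5, lambda = 0),
                   class = "psychometric_fit")
  c_star <- threshold_at_criterion(fit)
  expect_equal(c_star, 0.02 * (-log(1 - (sqrt(0.5) - 0.5) / 0.5)),
               tolerance = 1e-12)
  expect_equal(c_star, 0.0107, tolerance = 1e-2)

  set.seed(21)
  for (i in 1:10) {
    f <- structure(list(alpha = runif(1, 0.005, 0.05),
                        beta = runif(1, 0.8, 6), gamma = 0.5,
                        lambda = runif(1, 0, 0.05)),
                   class = "psychometric_fit")
    crit <- runif(1, 0.55, 0.9)
    cs <- threshold_at_criterion(f, crit)
    expect_equal(predict_fit(f, cs), crit, tolerance = 1e-9)
    # independent numeric inversion
    oracle <- uniroot(function(x) predict_fit(f, x) - crit,
                      c(1e-8, 10), tol = 1e-12)$root
    expect_equal(cs, oracle, tolerance = 1e-7)
  }

  expect_error(threshold_at_criterion(fit, 0.5), "not attainable")
  lapsy <- structure(list(alpha = 0.02, beta = 2, gamma = 0.5, lambda = 0.05),
                     class = "psychometric_fit")
  expect_error(threshold_at_criterion(lapsy, 0.96), "0.95")
})

test_that("JNDs multiply threshold contrast by background content", {
  expect_equal(jnd(0.0135, 100), 1.35)
  expect_equal(jnd(0.02, 1), 0.02)
  expect_equal(jnd(0.02, 50), 2 * jnd(0.02, 25))
  expect_error(jnd(-0.01, 1), "positive")
})

test_that("JND normalization fixes the low-condition median at unity", {
  v <- normalize_jnds(c(2, 2, 2, 2, 5), c(rep("low", 4), "high"))
  expect_equal(v[1:4], rep(1, 4))
  v2 <- normalize_jnds(c(1, 2, 3, 4, 5), c(rep("low", 4), "high"))
  expect_equal(median(v2[1:5][c(TRUE, TRUE, TRUE, TRUE, FALSE)]), 1)
  expect_equal(v2[5], 2)
  expect_error(normalize_jnds(c(0, 0), c("low", "low")), "positive")
  # invariant to the mean-vs-sum LMS convention: contents differ by x3
  exc <- exc_vec(1, 2, 3)
  j_mean <- jnd(0.013, lms_content(exc))
  j_sum <- jnd(0.013, lms_content(exc, "sum"))
  expect_equal(normalize_jnds(rep(j_mean, 4), rep("low", 4)),
               normalize_jnds(rep(j_sum, 4), rep("low", 4)))
})

test_that("within-session differences require complete pairs and respect labels", {
  res <- data.frame(session = rep(1:4, each = 2),
                    condition = rep(c("low", "high"), 4),
                    normalized_jnd = rep(1, 8))
  d <- within_session_differences(res)
  expect_equal(d$difference, rep(0, 4))
  expect_error(within_session_differences(res[-1, ]), "session 1")
})

test_that("summary statistics follow the type-7 quantile rule and notch CI", {
  st <- summarize_stats(c(1, 2, 3, 4))
  expect_equal(st$median, 2.5)
  expect_equal(st$iqr, 1.5)  # type-7: Q1 = 1.75, Q3 = 3.25
  expect_equal(st$ci_low, 2.5 - 1.58 * 1.5 / 2)
  expect_equal(st$ci_high, 2.5 + 1.58 * 1.5 / 2)

  cst <- summarize_stats(rep(7, 5))
  expect_equal(cst$iqr, 0)
  expect_equal(cst$ci_low, 7); expect_equal(cst$ci_high, 7)

  shifted <- summarize_stats(c(1, 2, 3, 4) + 10)
  expect_equal(shifted$median, st$median + 10)
  expect_equal(shifted$iqr, st$iqr)
  expect_equal(shifted$ci_low, st$ci_low + 10)
  expect_error(summarize_stats(3), "at least 2")
})
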