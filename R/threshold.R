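# Maximum-likelihood cumulative-Weibull psychometric fitting and the
# threshold / JND statistics derived from it.
#
# p(c) = gamma + (1 - gamma - lambda) * (1 - exp(-(c / alpha)^beta))
# with the guess rate gamma fixed at 0.5 for the two-interval forced-choice
# task, the lapse rate lambda free in [0, 0.05], and the slope beta
# unrestricted.

#' Cumulative Weibull psychometric function
#'
#' @param contrast Stimulus contrast(s), >= 0.
#' @param alpha Scale (threshold) parameter, > 0, contrast units.
#' @param beta Slope parameter, > 0.
#' @param gamma Guess rate (default 0.5 for 2IFC).
#' @param lambda Lapse rate in [0, 0.05].
#' @return Probability of a correct response at each contrast.
#' @export
weibull_prob <- function(contrast, alpha, beta, gamma = 0.5, lambda = 0) {
  gamma + (1 - gamma - lambda) * (1 - exp(-(contrast / alpha)^beta))
}

weibull_nll <- function(alpha, beta, lambda, contrast, n_correct, n_total,
                        gamma = 0.5) {
  p <- weibull_prob(contrast, alpha, beta, gamma, lambda)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(n_correct * log(p) + (n_total - n_correct) * log(1 - p))
}

aggregate_trials <- function(records) {
  if (!all(c("nominal_contrast", "correct") %in% names(records))) {
    stop("records must contain nominal_contrast and correct columns")
  }
  agg <- stats::aggregate(cbind(n_correct = as.integer(records$correct),
                                n_total = rep(1L, nrow(records))),
                          by = list(contrast = records$nominal_contrast), sum)
  agg[order(agg$contrast), ]
}

#' Fit a cumulative Weibull psychometric function by maximum likelihood
#'
#' Maximizes the Bernoulli likelihood over (alpha, beta, lambda) with the
#' guess rate fixed at 0.5 and lambda bounded in [0, 0.05]. A multistart
#' scheme seeds a bounded quasi-Newton optimizer (L-BFGS-B on log alpha,
#' log beta, lambda) from the best points of a 5 x 5 x 3 coarse grid; ties
#' between equal-likelihood optima break toward the lowest alpha.
#'
#' @param records Trial records with columns `nominal_contrast` and
#'   `correct` (as from [run_block()]), or a pre-aggregated data frame with
#'   columns `contrast`, `n_correct`, `n_total`.
#' @param gamma Fixed guess rate (default 0.5).
#' @param lambda_max Upper bound of the lapse rate (default 0.05; bounds are
#'   treated as closed).
#' @param n_starts Number of grid points carried into the quasi-Newton
#'   refinement stage (the full grid is always scored).
#' @return An object of class `psychometric_fit` with elements `alpha`,
#'   `beta`, `gamma`, `lambda`, `neg_log_likelihood`, `convergence`, `data`.
#' @export
fit_weibull <- function(records, gamma = 0.5, lambda_max = 0.05,
                        n_starts = 3L) {
  agg <- if (all(c("contrast", "n_correct", "n_total") %in% names(records))) {
    records
  } else {
    aggregate_trials(records)
  }
  k <- sum(agg$n_correct); n <- sum(agg$n_total)
  if (k == n || k == 0) {
    stop("degenerate data: all responses ", if (k == n) "correct" else "incorrect",
         "; the likelihood is maximized on the guess/lapse boundary and alpha is unidentified")
  }
  if (sum(agg$n_total > 0) < 2L) {
    stop("at least 2 distinct contrast levels are required")
  }

  cpos <- agg$contrast[agg$contrast > 0]
  arange <- if (length(cpos)) range(cpos) else c(1e-3, 5e-2)
  alpha_grid <- exp(seq(log(max(arange[1] / 2, 1e-5)),
                        log(max(arange[2] * 2, 2e-3)), length.out = 5))
  beta_grid <- c(0.5, 1.5, 3, 5, 8)
  lambda_grid <- c(0, lambda_max / 2, lambda_max)
  grid <- expand.grid(alpha = alpha_grid, beta = beta_grid,
                      lambda = lambda_grid)
  grid$nll <- mapply(function(a, b, l)
    weibull_nll(a, b, l, agg$contrast, agg$n_correct, agg$n_total, gamma),
    grid$alpha, grid$beta, grid$lambda)
  grid <- grid[order(grid$nll, grid$alpha), ]

  obj <- function(par) {
    weibull_nll(exp(par[1]), exp(par[2]), par[3],
                agg$contrast, agg$n_correct, agg$n_total, gamma)
  }
  best <- NULL
  for (i in seq_len(min(n_starts, nrow(grid)))) {
    start <- c(log(grid$alpha[i]), log(grid$beta[i]), grid$lambda[i])
    fit <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B",
                   lower = c(log(1e-5), log(0.05), 0),
                   upper = c(log(1), log(50), lambda_max),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 && fit$par[1] < best$par[1])) {
      best <- fit
    }
  }
  if (is.null(best)) stop("psychometric fit failed from every start")

  structure(list(alpha = exp(best$par[1]), beta = exp(best$par[2]),
                 gamma = gamma, lambda = best$par[3],
                 neg_log_likelihood = best$value,
                 convergence = best$convergence, n_trials = n,
                 data = agg),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> alpha=%.5g beta=%.3g gamma=%.3g lambda=%.3g (nll %.3f, %d trials)\n",
              x$alpha, x$beta, x$gamma, x$lambda, x$neg_log_likelihood,
              x$n_trials))
  invisible(x)
}

#' Evaluate a fitted psychometric function
#' @param fit A `psychometric_fit`.
#' @param contrast Contrast(s).
#' @return Probability correct.
#' @export
predict_fit <- function(fit, contrast) {
  weibull_prob(contrast, fit$alpha, fit$beta, fit$gamma, fit$lambda)
}

#' Threshold contrast at a performance criterion
#'
#' Closed-form inversion of the fitted Weibull at the criterion proportion
#' correct (default sqrt(1/2), displayed as 70.71%):
#' `c* = alpha * (-log(1 - (criterion - gamma) / (1 - gamma - lambda)))^(1/beta)`.
#'
#' @param fit A `psychometric_fit`.
#' @param criterion Proportion correct, strictly between `gamma` and
#'   `1 - lambda`.
#' @return Threshold contrast.
#' @export
threshold_at_criterion <- function(fit, criterion = sqrt(0.5)) {
  ceiling <- 1 - fit$lambda
  if (criterion <= fit$gamma || criterion >= ceiling) {
    stop(sprintf(
      "criterion %.4f not attainable: the fitted function spans (%.4f, %.4f)",
      criterion, fit$gamma, ceiling))
  }
  q <- (criterion - fit$gamma) / (1 - fit$gamma - fit$lambda)
  fit$alpha * (-log(1 - q))^(1 / fit$beta)
}

#' Just-noticeable difference in excitation units
#'
#' Threshold contrast times the background LMS content: the absolute change
#' in combined cone excitation that is just detectable on that background.
#'
#' @param threshold_contrast Threshold Weber contrast (> 0).
#' @param background_lms_content Background LMS content (> 0), as from
#'   [lms_content()].
#' @return JND in excitation units.
#' @export
jnd <- function(threshold_contrast, background_lms_content) {
  if (any(threshold_contrast <= 0) || any(background_lms_content <= 0)) {
    stop("threshold contrast and background content must be positive")
  }
  threshold_contrast * background_lms_content
}

#' Normalize JNDs to the low-condition median
#'
#' Divides every JND by the median JND of the low condition, so the low
#' condition has median exactly 1 and high-condition values read as fold
#' changes.
#'
#' @param jnds Numeric JND values.
#' @param condition Character/factor vector, same length, with at least one
#'   value equal to `low_label`.
#' @param low_label Label of the reference condition (default "low").
#' @return Numeric vector of normalized JNDs.
#' @export
normalize_jnds <- function(jnds, condition, low_label = "low") {
  low <- jnds[condition == low_label]
  if (!length(low)) stop("no JNDs in the reference condition '", low_label, "'")
  m <- stats::median(low)
  if (!is.finite(m) || m <= 0) {
    stop("low-condition median JND must be positive; got ", m)
  }
  jnds / m
}

#' Within-session high-minus-low differences of normalized JNDs
#'
#' @param results Data frame with columns `session`, `condition`,
#'   `normalized_jnd`; each session must contain exactly one `low` and one
#'   `high` value.
#' @param low_label,high_label Condition labels.
#' @return Data frame with columns `session` and `difference`
#'   (high - low).
#' @export
within_session_differences <- function(results, low_label = "low",
                                       high_label = "high") {
  out <- lapply(split(results, results$session), function(d) {
    lo <- d$normalized_jnd[d$condition == low_label]
    hi <- d$normalized_jnd[d$condition == high_label]
    if (length(lo) != 1L || length(hi) != 1L) {
      stop("session ", d$session[1L],
           " is not a complete low/high pair (found ", length(lo), " low, ",
           length(hi), " high)")
    }
    data.frame(session = d$session[1L], difference = hi - lo)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Median, IQR and the median-based confidence interval
#'
#' Median and IQR use the type-7 (linear interpolation) quantile rule; the
#' 95% CI about the median is `median +/- (1.58 * IQR) / sqrt(n)`.
#'
#' @param values Numeric vector, n >= 2.
#' @return List with `median`, `iqr`, `ci_low`, `ci_high`, `n`.
#' @export
summarize_stats <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("at least 2 values are required for a CI")
  m <- stats::median(values)
  iqr <- stats::IQR(values, type = 7)
  hw <- 1.58 * iqr / sqrt(n)
  list(median = m, iqr = iqr, ci_low = m - hw, ci_high = m + hw, n = n)
}
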