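#' Calculated-versus-actual regression summary
#'
#' Ordinary least squares of the model-calculated resection parameters on
#' the actual (measured) ones, `calculated = a + b * actual`, with the
#' quality metrics used to rate the model: residual standard deviation
#' `S = sqrt(RSS / (n - 2))`, average approximation error
#' `Abar = (100 / n) * sum(|e_i / y_i|)` over nonzero responses (mean
#' absolute percentage error), `R^2`, the F statistic for the slope, and t
#' statistics for both coefficients. A model is rated "good" when `Abar`
#' does not exceed the threshold (default 10 percent).
#'
#' @param actual Measured values.
#' @param calculated Model-predicted values (same units and length; >= 3
#'   pairs).
#' @param good_threshold_pct "Good model" gate on `Abar`, percent.
#' @return An object of class `regression_summary` with fields
#'   `intercept`, `slope`, `residual_sd`, `approx_error_pct`, `r_squared`,
#'   `f_statistic`, `t_statistics`, `residuals`, `fitted`, `n`,
#'   `n_excluded_zero_y`, `good_model`, `good_threshold_pct` and the input
#'   vectors.
#' @export
fit_regression <- function(actual, calculated, good_threshold_pct = 10) {
  actual <- as.numeric(actual)
  calculated <- as.numeric(calculated)
  n <- length(actual)
  if (length(calculated) != n) stop_input("inputs must have equal length")
  if (n < 3L) stop_input("need at least 3 pairs")
  if (!all(is.finite(actual)) || !all(is.finite(calculated))) {
    stop_input("inputs must be finite")
  }
  if (stats::var(actual) == 0) stop_input("constant x: regression undefined")
  fit <- stats::lm(calculated ~ actual)
  e <- stats::residuals(fit)
  rss <- sum(e^2)
  tss <- sum((calculated - mean(calculated))^2)
  s <- sqrt(rss / (n - 2))
  nz <- calculated != 0
  abar <- if (any(nz)) 100 * mean(abs(e[nz] / calculated[nz])) else NA_real_
  if (!all(nz)) {
    warning(sum(!nz), " zero response value(s) excluded from Abar")
  }
  # statistics computed from first principles so a perfect fit (RSS = 0)
  # yields clean limits (R^2 = 1, infinite F) rather than warnings
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  fstat <- if (rss > 0) (tss - rss) / (rss / (n - 2)) else Inf
  X <- cbind(1, actual)
  se <- sqrt(diag(solve(crossprod(X))) * rss / (n - 2))
  tstat <- ifelse(se > 0, stats::coef(fit) / se,
                  ifelse(stats::coef(fit) == 0, 0, Inf))
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 residual_sd = s,
                 approx_error_pct = abar,
                 r_squared = r2,
                 f_statistic = fstat,
                 t_statistics = unname(tstat),
                 residuals = unname(e),
                 fitted = unname(stats::fitted(fit)),
                 n = n,
                 n_excluded_zero_y = sum(!nz),
                 good_model = is.finite(abar) && abar <= good_threshold_pct,
                 good_threshold_pct = good_threshold_pct,
                 actual = actual, calculated = calculated),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("y = %.4g + %.4g x  (n = %d)\n", x$intercept, x$slope, x$n))
  cat(sprintf("  S = %.4g   Abar = %.3g%%   R^2 = %.4g\n",
              x$residual_sd, x$approx_error_pct, x$r_squared))
  cat(sprintf("  model quality: %s (gate: Abar <= %g%%)\n",
              if (x$good_model) "good" else "not good", x$good_threshold_pct))
  invisible(x)
}

#' Residual diagnostics for the regression
#'
#' A well-specified regression leaves residuals that look random: mean
#' zero (exact for OLS with intercept), no serial structure. Returns the
#' residual list with the lag-1 autocorrelation and a runs-count sign
#' statistic (observed number of sign runs versus the `n/2 + 1` expected
#' for random signs), plus the data needed for a residual plot.
#'
#' @param summary A [fit_regression()] result.
#' @return List with `residuals`, `mean`, `lag1_autocorrelation`,
#'   `runs_observed`, `runs_expected`, `plot_data` (data frame
#'   fitted/residual).
#' @export
residual_diagnostics <- function(summary) {
  stopifnot(inherits(summary, "regression_summary"))
  e <- summary$residuals
  n <- length(e)
  lag1 <- if (n >= 3 && stats::sd(e) > 0) {
    stats::cor(e[-1], e[-n])
  } else {
    NA_real_
  }
  sgn <- sign(e)
  sgn <- sgn[sgn != 0]
  runs <- if (length(sgn)) 1L + sum(diff(sgn) != 0) else 0L
  list(residuals = e,
       mean = mean(e),
       lag1_autocorrelation = lag1,
       runs_observed = runs,
       runs_expected = n / 2 + 1,
       plot_data = data.frame(fitted = summary$fitted, residual = e))
}

#' Regression adequacy tests
#'
#' Fisher's F test for overall regression significance and Student's t
#' tests for each coefficient, against critical values at level `alpha`.
#'
#' @param summary A [fit_regression()] result.
#' @param alpha Significance level in (0, 1).
#' @return List with `f_statistic`, `f_critical`, `f_significant`,
#'   `t_statistics`, `t_critical`, `t_significant` (intercept, slope),
#'   `df_residual`, `alpha`.
#' @export
adequacy_tests <- function(summary, alpha = 0.05) {
  stopifnot(inherits(summary, "regression_summary"))
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  df2 <- summary$n - 2L
  if (df2 < 1L) stop_input("too few observations for adequacy tests")
  f_crit <- stats::qf(1 - alpha, 1, df2)
  t_crit <- stats::qt(1 - alpha / 2, df2)
  list(f_statistic = summary$f_statistic,
       f_critical = f_crit,
       f_significant = summary$f_statistic > f_crit,
       t_statistics = summary$t_statistics,
       t_critical = t_crit,
       t_significant = abs(summary$t_statistics) > t_crit,
       df_residual = df2,
       alpha = alpha)
}
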