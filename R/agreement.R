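#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors, n >= 3, each with nonzero
#'   variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  check_xy(x, y, min_n = 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

check_xy <- function(x, y, min_n = 2L) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop("`x` and `y` must be equal-length numeric vectors", call. = FALSE)
  }
  if (length(x) < min_n) {
    stop("need at least ", min_n, " observations", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  invisible(NULL)
}

#' Ordinary least-squares fit with 95% confidence intervals
#'
#' Fits y = intercept + slope * x by least squares and returns the
#' coefficients with t-based confidence intervals on n - 2 residual
#' degrees of freedom. R-squared equals the squared Pearson correlation.
#' The confidence level defaults to 95%, the level used for every
#' interval in the accompanying analyses.
#'
#' @param x Predictor, nonzero variance.
#' @param y Response.
#' @param conf_level Confidence level for the intervals.
#' @return A list of class `pht_ols`: `slope`, `intercept`,
#'   `slope_se`, `intercept_se`, `slope_ci95`, `intercept_ci95`,
#'   `r_squared`, `n`, `residual_df`.
#' @export
ols_fit <- function(x, y, conf_level = 0.95) {
  check_xy(x, y, min_n = 3L)
  if (stats::sd(x) == 0) {
    stop("degenerate design: `x` has zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  # exact fits trigger a "perfect fit" note in summary.lm; they are valid
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  ci <- suppressWarnings(stats::confint(fit, level = conf_level))
  # R^2 via the correlation when defined; 1 for an exact horizontal line
  r2 <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)^2
  structure(
    list(slope = unname(cf["x"]), intercept = unname(cf["(Intercept)"]),
         slope_se = unname(se["x"]), intercept_se = unname(se["(Intercept)"]),
         slope_ci95 = unname(ci["x", ]),
         intercept_ci95 = unname(ci["(Intercept)", ]),
         r_squared = r2, n = length(x),
         residual_df = stats::df.residual(fit),
         conf_level = conf_level),
    class = "pht_ols"
  )
}

#' @export
print.pht_ols <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): y = %.4g + %.4g x, R^2 = %.3f\n",
              x$n, x$intercept, x$slope, x$r_squared))
  cat(sprintf("  %g%% CI slope (%.4g, %.4g), intercept (%.4g, %.4g)\n",
              100 * x$conf_level, x$slope_ci95[1], x$slope_ci95[2],
              x$intercept_ci95[1], x$intercept_ci95[2]))
  invisible(x)
}

#' Two-sided t-test of the regression slope against a null value
#'
#' Tests slope = `null_slope` (typically 1, the line of identity, or 0,
#' no relationship) with t = (slope - null) / se on the fit's residual
#' degrees of freedom. The alpha = 0.05 decision coincides with whether
#' the null value lies outside the 95% confidence interval. A zero
#' standard error (exact fit) yields p = 0 when the slope differs from
#' the null and p = 1 when it equals it.
#'
#' @param fit A `pht_ols` from [ols_fit()].
#' @param null_slope Null-hypothesis slope value.
#' @return A list with `t`, `df`, and `p`.
#' @export
slope_test <- function(fit, null_slope = 1) {
  if (!inherits(fit, "pht_ols")) {
    stop("`fit` must come from ols_fit()", call. = FALSE)
  }
  if (fit$residual_df < 1L) stop("no residual degrees of freedom",
                                 call. = FALSE)
  # a numerically exact fit leaves only rounding noise in the residuals
  if (fit$slope_se <= 1e-12 * max(1, abs(fit$slope))) {
    message("slope_test: zero slope standard error (exact fit)")
    p <- if (abs(fit$slope - null_slope) <= 1e-8 * max(1, abs(null_slope)))
      1 else 0
    return(list(t = if (p == 1) 0 else Inf * sign(fit$slope - null_slope),
                df = fit$residual_df, p = p))
  }
  tstat <- (fit$slope - null_slope) / fit$slope_se
  list(t = tstat, df = fit$residual_df,
       p = 2 * stats::pt(abs(tstat), df = fit$residual_df,
                         lower.tail = FALSE))
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are `x - y` in absolute mode, or
#' `100 * (x - y) / ((x + y)/2)` in percent mode; the bias is their mean
#' and the limits of agreement are bias +/- 1.96 standard deviations.
#'
#' @param x,y Paired measurements, n >= 2.
#' @param mode `"absolute"` or `"percent"`.
#' @return A list with `mode`, `bias`, `sd`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(x, y, mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  check_xy(x, y, min_n = 2L)
  if (mode == "absolute") {
    d <- x - y
  } else {
    denom <- (x + y) / 2
    if (any(denom == 0)) {
      stop("percent bias undefined: a pairwise mean is zero", call. = FALSE)
    }
    d <- 100 * (x - y) / denom
  }
  bias <- mean(d)
  s <- stats::sd(d)
  list(mode = mode, bias = bias, sd = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       n = length(d))
}

#' Regression of a method difference on a covariate
#'
#' Convenience wrapper: [ols_fit()] of the difference series (e.g.
#' total/10 minus free phenytoin) on a covariate such as albumin or
#' age. A nonzero slope indicates the disagreement between methods
#' varies systematically with the covariate.
#'
#' @param diff Difference series (response).
#' @param covariate Covariate (predictor).
#' @inheritParams ols_fit
#' @return A `pht_ols`.
#' @export
diff_vs_covariate <- function(diff, covariate, conf_level = 0.95) {
  ols_fit(covariate, diff, conf_level = conf_level)
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition:
#' F = (SS_between / df_between) / (SS_within / df_within).
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor), >= 2 non-empty
#'   groups and total n greater than the number of groups.
#' @return A list with `F`, `df_between`, `df_within`, and `p`.
#' @export
group_anova <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (!is.numeric(values) || length(values) != length(groups)) {
    stop("`values` and `groups` must have equal length", call. = FALSE)
  }
  k <- nlevels(groups)
  if (k < 2L) stop("ANOVA needs at least two groups", call. = FALSE)
  if (length(values) <= k) {
    stop("total n must exceed the number of groups", call. = FALSE)
  }
  aov_tab <- stats::anova(stats::lm(values ~ groups))
  Fval <- aov_tab[["F value"]][1L]
  df_b <- aov_tab[["Df"]][1L]
  df_w <- aov_tab[["Df"]][2L]
  # an exact within-group fit gives 0/0; identical groups mean F = 0
  if (is.nan(Fval)) Fval <- 0
  list(F = Fval, df_between = df_b, df_within = df_w,
       p = stats::pf(Fval, df_b, df_w, lower.tail = FALSE))
}

#' Two-sample t-test
#'
#' Pooled-variance (Student) two-sample t-test with
#' df = n_a + n_b - 2 by default, matching the classical presentation;
#' Welch's unequal-variance form is available via `welch = TRUE`. Two
#' zero-variance groups with different means give an infinite t and
#' p = 0, with a message.
#'
#' @param values_a,values_b Numeric vectors, each n >= 2.
#' @param welch Use the Welch-Satterthwaite correction.
#' @return A list with `t`, `df`, and `p` (two-sided).
#' @export
unpaired_t <- function(values_a, values_b, welch = FALSE) {
  if (!is.numeric(values_a) || !is.numeric(values_b) ||
      length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least two numeric values", call. = FALSE)
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(list(t = 0, df = length(values_a) + length(values_b) - 2L,
                  p = 1))
    }
    message("unpaired_t: zero variance in both groups; p -> 0")
    return(list(t = Inf * sign(mean(values_a) - mean(values_b)),
                df = length(values_a) + length(values_b) - 2L, p = 0))
  }
  res <- stats::t.test(values_a, values_b, var.equal = !welch)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
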