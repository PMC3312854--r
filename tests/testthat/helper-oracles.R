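# Independent oracles, kept deliberately naive: exhaustive enumeration and
# textbook closed forms, never calling the functions they check.

# Two-sided Fisher exact p for [[a,b],[c,d]] by enumerating every table
# with the observed margins and summing hypergeometric probabilities no
# larger than the observed table's.
fisher_enumeration_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  prob <- vapply(support, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- prob[support == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# OLS slope/intercept and standard errors from the raw normal-equation
# sums, plus t-based confidence intervals.
ols_sums_oracle <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  ssx <- sxx - sx^2 / n
  se_slope <- sqrt(s2 / ssx)
  se_intercept <- sqrt(s2 * (1 / n + (sx / n)^2 / ssx))
  tcrit <- qt(1 - (1 - conf_level) / 2, df = n - 2)
  list(slope = slope, intercept = intercept,
       se_slope = se_slope, se_intercept = se_intercept,
       slope_ci = slope + c(-1, 1) * tcrit * se_slope,
       intercept_ci = intercept + c(-1, 1) * tcrit * se_intercept)
}

# Pearson chi-squared computed term by term from observed and expected.
chisq_termwise_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  list(statistic = sum((m - e)^2 / e),
       df = (nrow(m) - 1) * (ncol(m) - 1))
}

# One-way ANOVA F from explicit sums of squares.
anova_ss_oracle <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((values - means[groups])^2)
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  (ss_b / df_b) / (ss_w / df_w)
}

# Pooled-variance two-sample t from the textbook formula.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}
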