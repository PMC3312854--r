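test_that("Pearson correlation behaves on exact and hand-computed cases", {
  x <- c(0.3, 1.1, 2.7, 4.0, 5.5)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  # covariance cancels by hand: sum((x-1)(y-1/3)) = 0
  expect_equal(pearson_r(c(0, 1, 2), c(0, 1, 0)), 0.0)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("OLS matches the normal-equations oracle on random fixtures", {
  exact <- ols_fit(1:5, 2 + 3 * (1:5))
  expect_equal(exact$slope, 3)
  expect_equal(exact$intercept, 2)
  expect_equal(exact$r_squared, 1)
  expect_equal(diff(exact$slope_ci95), 0, tolerance = 1e-12)
  expect_error(ols_fit(rep(2, 5), 1:5), "zero variance")
  expect_error(ols_fit(1:2, 1:2), "at least 3")

  set.seed(31)
  for (i in 1:100) {
    n <- sample(4:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- runif(1, -2, 2) + runif(1, -3, 3) * x + rnorm(n, sd = 0.5)
    fit <- ols_fit(x, y)
    want <- ols_sums_oracle(x, y)
    expect_equal(fit$slope, want$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, want$intercept, tolerance = 1e-9)
    expect_equal(fit$slope_se, want$se_slope, tolerance = 1e-9)
    expect_equal(fit$slope_ci95, want$slope_ci, tolerance = 1e-9)
    expect_equal(fit$intercept_ci95, want$intercept_ci, tolerance = 1e-9)
    expect_equal(fit$r_squared, pearson_r(x, y)^2, tolerance = 1e-12)
    expect_equal(fit$residual_df, n - 2L)
  }
})

test_that("the identity-line t-test agrees with the confidence-interval decision", {
  x <- c(0.5, 1.2, 2.2, 3.1, 4.9)
  perfect <- ols_fit(x, x)
  expect_message(res <- slope_test(perfect, 1), "zero slope standard error")
  expect_equal(res$p, 1)

  set.seed(32)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    xs <- rnorm(n)
    ys <- 0.2 + runif(1, 0.7, 1.3) * xs + rnorm(n, sd = 0.4)
    fit <- ols_fit(xs, ys)
    st <- slope_test(fit, 1)
    outside_ci <- 1 < fit$slope_ci95[1] || 1 > fit$slope_ci95[2]
    expect_identical(st$p < 0.05, outside_ci)
    # t from the oracle's standard error
    want <- ols_sums_oracle(xs, ys)
    expect_equal(st$t, (want$slope - 1) / want$se_slope, tolerance = 1e-9)
  }
})

test_that("Bland-Altman bias and limits follow their definitions", {
  x <- c(1.2, 2.5, 3.1, 4.4)
  same <- bland_altman(x, x, "absolute")
  expect_equal(same$bias, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)

  shifted <- bland_altman(x + 0.5, x, "absolute")
  expect_equal(shifted$bias, 0.5)
  expect_equal(shifted$sd, 0)

  # percent mode with mean denominator: (2,1) and (4,2) both differ 66.67%
  pct <- bland_altman(c(2, 4), c(1, 2), "percent")
  expect_equal(pct$bias, 100 * 1 / 1.5)
  expect_equal(pct$sd, 0)
  expect_error(bland_altman(c(1, 2), c(-1, 2), "percent"), "mean is zero")

  # absolute bias is exactly the difference in means
  set.seed(33)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(bland_altman(a, b, "absolute")$bias, mean(a) - mean(b))
  ba <- bland_altman(a, b, "absolute")
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
})

test_that("difference-vs-covariate regression is OLS of the difference series", {
  alb <- seq(1.5, 5, length.out = 20)
  flat <- diff_vs_covariate(rep(0.4, 20), alb)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$intercept, 0.4, tolerance = 1e-12)

  # generator algebra: free = total * 0.1/(0.2 alb + 0.1), so total/10 - free
  # falls with rising free fraction -> negative intercept, positive slope
  set.seed(34)
  albs <- runif(300, 1.2, 5.5)
  totals <- rlnorm(300, log(12), 0.4)
  free <- totals * 0.1 / (0.2 * albs + 0.1)
  fit <- diff_vs_covariate(totals / 10 - free, albs)
  expect_lt(fit$intercept, 0)
  expect_gt(fit$slope, 0)
})

test_that("one-way ANOVA matches explicit sums of squares and the t-test identity", {
  vals <- rep(c(1, 2, 3), times = 3)
  grp <- rep(c("a", "b", "c"), each = 3)
  # identical group distributions
  same <- group_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$F, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  expect_error(group_anova(1:5, rep("a", 5)), "two groups")

  set.seed(35)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- sample((k + 2):60, 1)
    groups <- sample(letters[1:k], n, TRUE)
    if (length(unique(groups)) < 2) next
    values <- rnorm(n) + as.integer(factor(groups)) * 0.3
    got <- group_anova(values, groups)
    expect_equal(got$F, anova_ss_oracle(values, groups), tolerance = 1e-9)
  }

  # two-group F equals the squared pooled t
  for (i in 1:20) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), mean = 0.5)
    tt <- unpaired_t(a, b)
    an <- group_anova(c(a, b), rep(c("a", "b"), c(length(a), length(b))))
    expect_equal(an$F, tt$t^2, tolerance = 1e-9)
    expect_equal(an$p, tt$p, tolerance = 1e-9)
  }
})

test_that("the pooled t-test matches the textbook formula and handles edge cases", {
  same <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_message(zed <- unpaired_t(c(0, 0), c(1, 1)), "zero variance")
  expect_equal(zed$p, 0)
  expect_true(is.infinite(zed$t))
  expect_error(unpaired_t(1, c(1, 2)), "at least two")

  set.seed(36)
  a <- rnorm(12); b <- rnorm(9, 0.7)
  got <- unpaired_t(a, b)
  expect_equal(got$t, pooled_t_oracle(a, b), tolerance = 1e-9)
  expect_equal(got$df, 19)
  # Welch flag reduces to a different df
  expect_false(unpaired_t(a, b, welch = TRUE)$df == 19)
})
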