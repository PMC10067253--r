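# ICC, paired t, Bland-Altman, Pearson/regression, Shapiro-Wilk.

fixed_6x2 <- rbind(c(10, 11), c(12, 14), c(9, 10), c(15, 15), c(20, 18), c(13, 12))

test_that("ICC is 1 for duplicated sessions and matches the mean-squares oracle", {
  set.seed(1)
  a <- rnorm(12, 50, 8)
  expect_equal(icc_test_retest(cbind(a, a))$icc, 1, tolerance = 1e-12)

  # oracle: direct mean-squares arithmetic, scalar loops, no shortcuts
  m <- fixed_6x2
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssr <- 0; for (i in 1:n) ssr <- ssr + k * (mean(m[i, ]) - grand)^2
  ssc <- 0; for (j in 1:k) ssc <- ssc + n * (mean(m[, j]) - grand)^2
  sse <- 0
  for (i in 1:n) for (j in 1:k) {
    sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
  }
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  res <- icc_test_retest(m)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-12)
  expect_equal(res$MSR, msr, tolerance = 1e-12)
  expect_equal(res$MSE, mse, tolerance = 1e-12)
})

test_that("ICC(2,1) and its CI reproduce an independent reference implementation", {
  # reference values computed with pingouin.intraclass_corr (ICC(A,1) row)
  res <- icc_test_retest(fixed_6x2)
  expect_equal(res$icc, 0.923928, tolerance = 1e-6)
  expect_equal(res$conf_low, 0.55, tolerance = 0.01)
  expect_equal(res$conf_high, 0.99, tolerance = 0.01)
  res3 <- icc_test_retest(fixed_6x2, model = "ICC3")
  expect_equal(res3$icc, 0.911323, tolerance = 1e-6)
  expect_equal(res3$conf_low, 0.50, tolerance = 0.01)
})

test_that("ICC is invariant under common affine rescaling of both sessions", {
  set.seed(2)
  subj <- rnorm(15, 40, 10)
  m <- cbind(subj + rnorm(15), subj + rnorm(15))
  base <- icc_test_retest(m)$icc
  expect_equal(icc_test_retest(3.7 * m + 11)$icc, base, tolerance = 1e-9)
})

test_that("ICC near zero for independent sessions; errors on bad designs", {
  set.seed(3)
  expect_lt(abs(icc_test_retest(cbind(rnorm(1000), rnorm(1000)))$icc), 0.1)
  expect_error(icc_test_retest(matrix(5, 6, 2)), "zero total variance")
  expect_error(icc_test_retest(matrix(rnorm(4), 2, 2)), "at least 3")
  expect_error(icc_test_retest(rbind(c(1, NA), c(2, 3), c(4, 5))), "missing")
  # long format accepted
  long <- data.frame(subject = rep(1:6, each = 2), session = rep(c("s1", "s2"), 6),
                     value = as.numeric(t(fixed_6x2)))
  expect_equal(icc_test_retest(long)$icc, icc_test_retest(fixed_6x2)$icc)
})

test_that("paired t reproduces the closed form and rejects degenerate input", {
  set.seed(4)
  b <- rnorm(10, 20, 3)
  a <- b + 0.5 + rnorm(10, 0, 0.2)  # mean shift plus jitter
  res <- paired_t(a, b)
  d <- a - b
  expect_equal(res$t_stat, mean(d) / (sd(d) / sqrt(10)))
  expect_equal(res$p_value, 2 * stats::pt(-abs(res$t_stat), 9))
  # exactly constant differences have zero SE: undefined by design
  expect_error(paired_t(b + 0.5, b), "zero difference variance")
  expect_error(paired_t(1, 2), "at least 2")
  expect_error(paired_t(c(1, 2), c(2, 3)), "zero difference variance")
})

test_that("Bland-Altman limits, outside counts and antisymmetry", {
  a <- c(3, 7, 1, 9, 4)
  ba <- bland_altman(a, a + 2)
  expect_equal(ba$summary$bias, -2)
  expect_equal(ba$summary$loa_low, ba$summary$loa_high)
  expect_equal(ba$summary$outside_count, 0L)

  set.seed(5)
  x <- rnorm(50); y <- rnorm(50)
  ab <- bland_altman(x, y)$summary
  ba2 <- bland_altman(y, x)$summary
  expect_equal(ab$bias, -ba2$bias)
  expect_equal(ab$loa_low, -ba2$loa_high)

  two <- bland_altman(c(1, 2), c(1.5, 2.2))$summary
  expect_equal(two$n, 2L)
  expect_equal(two$outside_count, 0L)
})

test_that("Pearson and regression match the textbook formulas", {
  a <- c(2, 4, 5, 7, 9)
  res <- pearson_and_regression(a, 2 * a + 1)
  expect_equal(res$pearson_r, 1, tolerance = 1e-12)
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_equal(res$intercept, 1, tolerance = 1e-12)

  expect_equal(pearson_and_regression(c(-1, 0, 1), c(1, -2, 1))$pearson_r, 0)

  set.seed(6)
  x <- rnorm(10, 5, 2); y <- 0.8 * x + rnorm(10)
  res2 <- pearson_and_regression(x, y)
  # independent scalar-arithmetic oracle
  r_o <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  slope_o <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(res2$pearson_r, r_o, tolerance = 1e-12)
  expect_equal(res2$slope, slope_o, tolerance = 1e-12)
  expect_equal(res2$intercept, mean(y) - slope_o * mean(x), tolerance = 1e-12)
  expect_equal(res2$r_squared, r_o^2, tolerance = 1e-12)
  expect_error(pearson_and_regression(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("Shapiro-Wilk wrapper enforces its domain", {
  set.seed(7)
  res <- shapiro_wilk(rnorm(100))
  expect_true(res$W > 0 && res$W <= 1)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(rnorm(2)), "3 <= n <= 5000")
  expect_error(shapiro_wilk(rnorm(5001)), "3 <= n <= 5000")
})

test_that("the full agreement battery ties the pieces together with tidiers", {
  set.seed(8)
  sa <- rnorm(22, 58, 12)
  dp <- sa * 0.85 + rnorm(22, 0, 5)
  res <- method_agreement(sa, dp)
  g <- glance(res)
  expect_equal(g$t_stat, paired_t(sa, dp)$t_stat)
  expect_equal(g$bias, mean(sa - dp))
  expect_equal(g$r_squared, g$pearson_r^2)
  td <- tidy(res)
  expect_true(all(c("pearson_r", "loa_low", "outside_count") %in% td$statistic))
  p <- ggplot2::autoplot(res$bland_altman)
  expect_s3_class(p, "ggplot")
})
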