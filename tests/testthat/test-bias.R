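test_that("bias of identical samples is exactly zero with p = 1", {
  x <- c(1.1, 1.2, 0.9, 1.05)
  res <- bias_test(x, x)
  expect_identical(res$mean_difference, 0)
  expect_identical(res$t_statistic, 0)
  expect_identical(res$p_value, 1)
  expect_identical(res$loa_low, 0)
  expect_identical(res$loa_high, 0)
})

test_that("constant nonzero differences give a certain bias (p = 0)", {
  res <- bias_test(rep(0.1, 4), rep(0, 4))
  expect_equal(res$mean_difference, 0.1)
  expect_identical(res$sd_difference, 0)
  expect_identical(res$p_value, 0)
  expect_identical(res$t_statistic, Inf)
})

test_that("bias_test matches the textbook paired t computation", {
  # worked 5-point example, checked against stats::t.test as the oracle
  x <- c(1.12, 1.25, 0.98, 1.31, 1.07)
  y <- c(1.05, 1.20, 1.01, 1.19, 1.02)
  res <- bias_test(x, y)
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(res$mean_difference, unname(tt$estimate), tolerance = 1e-12)
  expect_equal(res$t_statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  d <- x - y
  expect_equal(res$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(res$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
})

test_that("bias is antisymmetric with identical p-values", {
  set.seed(31)
  x <- rnorm(20, 1.1, 0.1)
  y <- x + rnorm(20, 0.05, 0.08)
  a <- bias_test(x, y)
  b <- bias_test(y, x)
  expect_identical(a$mean_difference, -b$mean_difference)
  expect_identical(a$p_value, b$p_value)
})

test_that("bias_comparison_test reduces to bias_test against a zero vector", {
  set.seed(32)
  d <- rnorm(15, 0.05, 0.1)
  cmp <- bias_comparison_test(d, rep(0, 15))
  ref <- bias_test(d, rep(0, 15))
  expect_identical(cmp$t_statistic, ref$t_statistic)
  expect_identical(cmp$p_value, ref$p_value)
  # and recovers a configured difference of biases
  set.seed(33)
  means <- replicate(200, {
    bias_comparison_test(rnorm(112, 0.05, 0.1),
                         rnorm(112, 0.13, 0.1))$mean_difference
  })
  sem <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - (-0.08)), 3 * sem)
})

test_that("bland_altman collapses for identical inputs and matches hand limits", {
  x <- c(1.0, 1.2, 1.4)
  ba <- bland_altman(x, x)
  expect_true(all(ba$data$difference == 0))
  expect_identical(ba$bias$loa_low, 0)
  # 3-point worked example
  y <- c(1.1, 1.15, 1.5)
  ba2 <- bland_altman(x, y, unit_ids = c("u1", "u2", "u3"))
  d <- x - y
  expect_equal(ba2$data$mean, (x + y) / 2)
  expect_equal(ba2$bias$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_identical(ba2$data$unit_id, c("u1", "u2", "u3"))
})

test_that("limits of agreement contain ~95% of large normal samples", {
  set.seed(34)
  x <- rnorm(10000, 1.1, 0.1)
  y <- x + rnorm(10000, 0.02, 0.05)
  ba <- bland_altman(x, y)
  inside <- mean(ba$data$difference >= ba$bias$loa_low &
                   ba$data$difference <= ba$bias$loa_high)
  expect_gt(inside, 0.93)
  expect_lt(inside, 0.97)
})

test_that("plot_bland_altman returns a ggplot with the three reference lines", {
  set.seed(35)
  ba <- bland_altman(rnorm(30, 1.1, 0.1), rnorm(30, 1.15, 0.1))
  p <- plot_bland_altman(ba)
  expect_s3_class(p, "ggplot")
})
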