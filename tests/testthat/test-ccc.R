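test_that("ccc handles the canonical identity and reversal cases", {
  expect_identical(ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  # perfect reversal with equal means and variances
  expect_equal(ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  # constant shift: equals 2 s_xy / (s_x^2 + s_y^2 + d^2) from the moments
  x <- c(1, 2, 3, 4)
  y <- c(1.1, 2.1, 3.1, 4.1)
  expect_lt(ccc(x, y), 1)
  expect_equal(ccc(x, y), oracle_ccc(x, y), tolerance = 1e-14)
})

test_that("ccc rejects invalid and degenerate input", {
  expect_error(ccc(1:3, 1:4), "same length")
  expect_error(ccc(1, 1), "at least 2")
  expect_error(ccc(c(1, NA, 3), c(1, 2, 3)), "missing")
  expect_error(ccc(c(2, 2, 2), c(2, 2, 2)), "undefined")
  # both constant but unequal means is defined (CCC = 0)
  expect_equal(ccc(c(1, 1, 1), c(2, 2, 2)), 0)
})

test_that("ccc is symmetric and bounded by the Pearson correlation", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3)) + rnorm(1)
    y <- 0.5 * x + rnorm(n, sd = runif(1, 0.2, 2)) + rnorm(1)
    expect_identical(ccc(x, y), ccc(y, x))
    expect_lte(abs(ccc(x, y)), abs(cor(x, y)) + 1e-12)
    expect_gte(ccc(x, y), -1)
    expect_lte(ccc(x, y), 1)
  }
  # equality with Pearson when means and variances match exactly
  set.seed(42)
  x <- rnorm(50)
  y <- 0.8 * x + rnorm(50)
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(x)
  expect_equal(ccc(x, y), cor(x, y), tolerance = 1e-12)
})

test_that("occc reduces to ccc for two columns and handles identical columns", {
  x <- c(1.1, 0.9, 1.3, 1.0, 1.2)
  expect_identical(occc(cbind(x, x, x)), 1)
  set.seed(7)
  for (i in 1:10) {
    m <- random_matrix(sample(5:30, 1), 2)
    expect_equal(occc(m), ccc(m[, 1], m[, 2]), tolerance = 1e-12)
  }
})

test_that("occc is the weighted mean of pairwise CCCs and permutation invariant", {
  set.seed(11)
  for (i in 1:10) {
    m <- random_matrix(10, 3)
    expect_equal(occc(m), oracle_occc_weighted(m), tolerance = 1e-12)
    perm <- sample(3)
    expect_equal(occc(m[, perm]), occc(m), tolerance = 1e-12)
  }
  expect_error(occc(matrix(1:6, ncol = 1)), "2 columns")
  expect_error(occc(matrix(2, 3, 3)), "undefined")
})

test_that("fisher transform round-trips, clamps at the boundary, and rejects |r| > 1", {
  expect_identical(fisher_z(0), 0)
  # atanh(0.88) evaluated through the log form
  expect_equal(fisher_z(0.88), 0.5 * log(1.88 / 0.12), tolerance = 1e-12)
  expect_equal(inverse_fisher(fisher_z(0.49)), 0.49, tolerance = 1e-12)
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_true(is.finite(z1))
  expect_error(fisher_z(1.01), "undefined")
})
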