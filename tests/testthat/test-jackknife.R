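test_that("jackknife SE matches a literal leave-one-out reimplementation", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    J <- sample(2:4, 1)
    m <- random_matrix(n, J)
    res <- jackknife_ci(m)
    expect_equal(res$se_z, oracle_jackknife_se(m, oracle_occc),
                 tolerance = 1e-12)
    expect_equal(res$estimate, oracle_occc(m), tolerance = 1e-12)
  }
})

test_that("grouped (subject-wise) deletion matches a grouped brute-force loop", {
  set.seed(22)
  m <- random_matrix(20, 2)
  groups <- rep(paste0("S", 1:10), each = 2)  # two limbs per subject
  res <- jackknife_ci(m, "ccc", groups = groups)
  expect_equal(res$n_units, 10L)
  expect_equal(res$se_z, oracle_jackknife_se(m, oracle_occc, groups),
               tolerance = 1e-12)
})

test_that("confidence bounds live on the tanh scale and contain the estimate", {
  set.seed(23)
  truth <- rnorm(20, 1.1, 0.1)
  m <- cbind(truth, truth + rnorm(20, sd = 1e-6))
  res <- suppressWarnings(jackknife_ci(m, "ccc"))
  expect_gt(res$estimate, 0.999)
  expect_lte(res$ci_high, 1)
  expect_lte(res$ci_low, res$estimate)
  expect_gte(res$ci_high, res$estimate)
  # symmetric z-scale construction
  mid <- fisher_z(res$estimate)
  expect_equal(tanh(mid - qnorm(0.975) * res$se_z), res$ci_low,
               tolerance = 1e-9)
})

test_that("perfect agreement yields SE zero with a clamping warning", {
  x <- c(1.0, 1.1, 1.2, 0.9, 1.3)
  expect_warning(res <- jackknife_ci(cbind(x, x), "ccc"), "clamped")
  expect_identical(res$estimate, 1)
  expect_identical(res$se_z, 0)
})

test_that("degenerate leave-one-out subsamples abort naming the unit", {
  m <- cbind(c(2, 2, 5), c(2, 2, 5))
  # deleting row 3 leaves two constant, equal columns
  expect_error(suppressWarnings(jackknife_ci(m, "ccc")),
               "degenerate leave-one-out.*'3'")
})

test_that("jackknife_ci validates its input contract", {
  m <- random_matrix(10, 3)
  expect_error(jackknife_ci(m, "ccc"), "exactly 2 columns")
  expect_error(jackknife_ci(m[1:2, ]), "at least 3 rows")
  expect_error(jackknife_ci(m, conf_level = 1.2), "conf_level")
  expect_error(jackknife_ci(m, groups = 1:4), "one entry per row")
})

test_that("self-comparison in the difference test gives zero difference, p = 1", {
  set.seed(24)
  m <- random_matrix(15, 3)
  res <- ccc_difference_test(m, 1:2, 1:2)
  expect_identical(res$difference, 0)
  expect_identical(res$p_value, 1)
  # overlapping column sets are permitted (shared reference column)
  res2 <- ccc_difference_test(m, c(1, 3), c(2, 3))
  expect_true(res2$p_value >= 0 && res2$p_value <= 1)
  expect_equal(res2$ccc_a, oracle_ccc(m[, 1], m[, 3]), tolerance = 1e-12)
})

test_that("difference sign is consistent with ccc_a - ccc_b on both scales", {
  set.seed(25)
  ref <- rnorm(60, 1.1, 0.1)
  m <- cbind(ref = ref, a = ref + rnorm(60, 0, 0.03),
             b = ref + rnorm(60, 0, 0.12))
  for (sc in c("fisher", "raw")) {
    res <- ccc_difference_test(m, c("a", "ref"), c("b", "ref"), scale = sc)
    expect_identical(sign(res$difference), sign(res$ccc_a - res$ccc_b))
  }
  # raw scale differences the coefficients directly
  res_raw <- ccc_difference_test(m, c("a", "ref"), c("b", "ref"),
                                 scale = "raw")
  expect_equal(res_raw$difference, res_raw$ccc_a - res_raw$ccc_b,
               tolerance = 1e-12)
})

test_that("the difference test detects a genuinely better method", {
  set.seed(26)
  rejections <- 0L
  n_reps <- 60
  for (i in seq_len(n_reps)) {
    truth <- rnorm(100)
    m <- cbind(ref = truth,
               a = truth + rnorm(100, 0, 0.33),  # population ccc ~ 0.9
               b = truth + rnorm(100, 0, 1.0))   # population ccc ~ 0.5
    res <- ccc_difference_test(m, c("a", "ref"), c("b", "ref"))
    if (res$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / n_reps, 0.5)
})
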