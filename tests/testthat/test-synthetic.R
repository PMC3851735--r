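test_that("the default design produces the expected record layout", {
  rec <- generate_study(synthetic_config(seed = 5))
  # 56 subjects x 2 limbs; 3 Doppler + 2 devices x 2 sets x 3 replicates
  expect_equal(nrow(rec), 56 * 2 * (3 + 2 * 2 * 3))
  expect_equal(dplyr::n_distinct(rec$subject_id), 56)
  expect_setequal(unique(rec$limb), c("left", "right"))
  counts <- dplyr::count(rec, .data$subject_id, .data$limb)
  expect_true(all(counts$n == 15))
  # Doppler once (set 1 only), automated devices in both sets
  expect_equal(sum(rec$device == "doppler" & rec$set_index == 2), 0)
  per_dev <- dplyr::count(rec, .data$device, .data$set_index)
  expect_true(all(per_dev$n[per_dev$device != "doppler"] == 56 * 2 * 3))
  expect_true(all(rec$replicate %in% 1:3))
  expect_equal(rec$abi, rec$ankle_mmHg / rec$brachial_mmHg, tolerance = 1e-9)
})

test_that("the observer schedule follows the inter/intra series design", {
  rec <- generate_study(synthetic_config(seed = 6))
  auto <- dplyr::filter(rec, .data$device != "doppler")
  obs <- auto |>
    dplyr::distinct(.data$subject_id, .data$series, .data$device,
                    .data$set_index, .data$observer) |>
    tidyr::pivot_wider(names_from = "set_index", values_from = "observer",
                       names_prefix = "set")
  inter <- dplyr::filter(obs, .data$series %in% 1:4)
  intra <- dplyr::filter(obs, .data$series %in% 5:8)
  expect_true(all(inter$set1 != inter$set2))
  expect_true(all(intra$set1 == intra$set2))
  # Doppler shares the observer of the first application
  dop <- rec |>
    dplyr::filter(.data$device == "doppler") |>
    dplyr::distinct(.data$subject_id, .data$observer)
  first_app <- dplyr::distinct(dplyr::filter(auto, .data$set_index == 1),
                               .data$subject_id, .data$observer)
  expect_identical(dop$observer[order(dop$subject_id)],
                   first_app$observer[order(first_app$subject_id)])
})

test_that("generation is deterministic given the seed", {
  a <- generate_study(synthetic_config(seed = 99))
  b <- generate_study(synthetic_config(seed = 99))
  expect_identical(a, b)
  c <- generate_study(synthetic_config(seed = 100))
  expect_false(identical(a$abi, c$abi))
})

test_that("invalid configurations are rejected listing the offenders", {
  expect_error(synthetic_config(n_subjects = 50),
               "sum\\(series_sizes\\)")
  expect_error(synthetic_config(true_abi_sd = -1), "true_abi_sd")
  expect_error(synthetic_config(limb_correlation = 1), "limb_correlation")
  err <- tryCatch(
    synthetic_config(n_subjects = 10, replicate_noise_sd = -2),
    error = conditionMessage
  )
  expect_match(err, "series_sizes")
  expect_match(err, "replicate_noise_sd")
})

test_that("noise-free generation reproduces the true ABI exactly on every device", {
  rec <- generate_study(noise_free_config(seed = 2))
  per_unit <- rec |>
    dplyr::group_by(.data$subject_id, .data$limb) |>
    dplyr::summarise(n_abi = dplyr::n_distinct(.data$abi), .groups = "drop")
  # every device, set and replicate yields the bitwise identical ABI
  expect_true(all(per_unit$n_abi == 1))
  expect_true(all(rec$abi > 0.3 & rec$abi < 1.6))
})

test_that("true ABI respects the truncation bounds under a wide configuration", {
  cfg <- synthetic_config(true_abi_mean = 1.4, true_abi_sd = 0.4,
                          replicate_noise_sd = 0, observer_effect_sd = 0,
                          seed = 8)
  rec <- generate_study(cfg)
  dop <- dplyr::filter(rec, .data$device == "doppler")
  expect_true(all(dop$abi < 1.6 + 1e-9))
  expect_true(all(dop$abi > 0.3 - 1e-9))
})

test_that("population_ccc is symmetric and exactly 1 in the noise-free limit", {
  cfg <- synthetic_config()
  expect_identical(population_ccc(cfg, "vicorder", "doppler"),
                   population_ccc(cfg, "doppler", "vicorder"))
  expect_identical(population_ccc(noise_free_config(), "vicorder", "doppler"),
                   1)
  expect_identical(population_within_set_occc(noise_free_config(), "doppler"),
                   1)
})

# n x 3 replicate-triplet ABI matrix of one device's first application
replicate_abi_matrix <- function(rec, dev) {
  wide <- rec |>
    dplyr::filter(.data$device == dev, .data$set_index == 1) |>
    dplyr::select("subject_id", "limb", "replicate", "abi") |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "abi")
  as.matrix(wide[, c("1", "2", "3")])
}

test_that("population_ccc matches a large Monte-Carlo estimate", {
  cfg <- synthetic_config(
    n_subjects = 10000L, series_sizes = rep(1250L, 8L),
    observer_effect_sd = 0, seed = 12
  )
  rec <- generate_study(cfg)
  for (dev in c("vicorder", "vascular_explorer")) {
    paired <- dplyr::inner_join(
      triplicate_mean(rec, dev), triplicate_mean(rec, "doppler"),
      by = c("subject_id", "limb"), suffix = c("_dev", "_dop")
    )
    mc <- ccc(paired$abi_dev, paired$abi_dop)
    expect_equal(population_ccc(cfg, dev, "doppler"), mc, tolerance = 0.01)
  }
  # within-set concordance target from the same draw
  expect_equal(population_within_set_occc(cfg, "vicorder"),
               occc(replicate_abi_matrix(rec, "vicorder")),
               tolerance = 0.01)
})

test_that("within-set concordance decreases as replicate noise grows", {
  grid <- c(2, 4, 8)
  pop <- vapply(grid, function(s) {
    population_within_set_occc(
      synthetic_config(replicate_noise_sd = s), "vicorder"
    )
  }, numeric(1))
  expect_true(all(diff(pop) < 0))
  est <- vapply(grid, function(s) {
    cfg <- synthetic_config(n_subjects = 2000L, series_sizes = rep(250L, 8L),
                            replicate_noise_sd = s, seed = 13)
    occc(replicate_abi_matrix(generate_study(cfg), "vicorder"))
  }, numeric(1))
  expect_true(all(diff(est) < 0))
})
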