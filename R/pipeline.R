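# Orchestration of the study analyses on long-format measurement data.
# One row per subject x limb x device x variant x observer x series x
# application set x replicate. Limb-level rows are the sampling units
# throughout (left and right side treated as independent).

.REQUIRED_COLS <- c("subject_id", "limb", "device", "variant", "observer",
                    "series", "set_index", "replicate",
                    "brachial_mmHg", "ankle_mmHg", "abi")

#' Read a long-format measurement CSV
#'
#' Reads and validates the canonical measurement schema: columns
#' `subject_id`, `limb` (left/right), `device`, `variant`, `observer`,
#' `series` (1-8), `set_index` (1-2), `replicate` (1-3), `brachial_mmHg`,
#' `ankle_mmHg`, `abi`. Whenever both pressures are present the ABI column
#' is cross-checked against `ankle_mmHg / brachial_mmHg` (relative
#' tolerance 1e-6) and recomputed when absent.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A validated tibble of measurement records.
#' @export
read_measurements <- function(path) {
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      limb = readr::col_character(),
      device = readr::col_character(),
      variant = readr::col_character(),
      observer = readr::col_character(),
      series = readr::col_integer(),
      set_index = readr::col_integer(),
      replicate = readr::col_integer(),
      brachial_mmHg = readr::col_double(),
      ankle_mmHg = readr::col_double(),
      abi = readr::col_double()
    ),
    progress = FALSE
  )
  validate_measurements(records)
}

#' @rdname read_measurements
#' @param records A tibble/data frame in the canonical schema (e.g. from
#'   [generate_study()]).
#' @export
validate_measurements <- function(records) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(.REQUIRED_COLS, names(records))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      stop("invalid ", what, " in rows: ",
           paste(utils::head(rows, 10), collapse = ", "),
           if (length(rows) > 10) " ..." else "", call. = FALSE)
    }
  }
  bad(!records$limb %in% c("left", "right"), "`limb` (must be left/right)")
  bad(!records$set_index %in% 1:2, "`set_index` (must be 1 or 2)")
  bad(!records$replicate %in% 1:3, "`replicate` (must be 1-3)")
  bad(!records$series %in% 1:8, "`series` (must be 1-8)")
  bad(records$device == "doppler" & records$set_index == 2L,
      "design: the Doppler reference is applied once (set 1 only)")

  # recompute ABI from pressures where possible; fill it in where absent
  have_both <- !is.na(records$brachial_mmHg) & !is.na(records$ankle_mmHg)
  recomputed <- records$ankle_mmHg[have_both] / records$brachial_mmHg[have_both]
  stated <- records$abi[have_both]
  mismatch <- !is.na(stated) &
    abs(stated - recomputed) > 1e-6 * pmax(1, abs(recomputed))
  if (any(mismatch)) {
    stop("`abi` disagrees with ankle_mmHg / brachial_mmHg in rows: ",
         paste(utils::head(which(have_both)[mismatch], 10), collapse = ", "),
         call. = FALSE)
  }
  records$abi[have_both] <- recomputed
  records
}

#' @rdname read_measurements
#' @export
write_measurements <- function(records, path) {
  records <- validate_measurements(records)
  readr::write_csv(records, path)
  invisible(path)
}

#' Per-limb means over a replicate triplet
#'
#' Averages the available replicates of one device application for each
#' limb-level record: the mean ABI, brachial and ankle pressures, and the
#' number of contributing replicates.
#'
#' @param records Measurement tibble in the canonical schema.
#' @param device,variant Device and variant to extract.
#' @param set_index Which application (1 or 2, default 1: the first
#'   measurement triplicate).
#' @return A tibble with one row per subject x limb carrying `abi`,
#'   `brachial_mmHg`, `ankle_mmHg` means, `n_replicates`, plus `observer`
#'   and `series` metadata.
#' @export
triplicate_mean <- function(records, device, variant = "raw", set_index = 1L) {
  dev <- device
  var <- variant
  set <- set_index
  records |>
    dplyr::filter(.data$device == dev, .data$variant == var,
                  .data$set_index == set, !is.na(.data$abi)) |>
    dplyr::group_by(.data$subject_id, .data$limb) |>
    dplyr::summarise(
      abi = mean(.data$abi),
      brachial_mmHg = mean(.data$brachial_mmHg),
      ankle_mmHg = mean(.data$ankle_mmHg),
      n_replicates = dplyr::n(),
      observer = dplyr::first(.data$observer),
      series = dplyr::first(.data$series),
      .groups = "drop"
    )
}

# wide n x 3 replicate matrix for one device application, complete cases
# only; errors if more than `max_excluded` of the records are incomplete.
.replicate_matrix <- function(records, device, variant, set_index,
                              max_excluded = 0.2) {
  dev <- device
  var <- variant
  set <- set_index
  wide <- records |>
    dplyr::filter(.data$device == dev, .data$variant == var,
                  .data$set_index == set) |>
    dplyr::select("subject_id", "limb", "replicate", "abi") |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "abi",
                       names_prefix = "rep")
  for (col in c("rep1", "rep2", "rep3")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  m_all <- as.matrix(wide[, c("rep1", "rep2", "rep3")])
  complete <- stats::complete.cases(m_all)
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message(n_excluded, " limb-record(s) excluded from within-set analysis of ",
            device, "/", variant, " (incomplete triplet).")
  }
  if (nrow(wide) == 0 || n_excluded > max_excluded * nrow(wide)) {
    stop("too many incomplete replicate triplets for ", device, "/", variant,
         " (", n_excluded, " of ", nrow(wide), ").", call. = FALSE)
  }
  list(
    m = m_all[complete, , drop = FALSE],
    units = paste(wide$subject_id, wide$limb, sep = ":")[complete],
    subject = wide$subject_id[complete],
    n_excluded = n_excluded
  )
}

#' Within-set agreement of replicate triplets
#'
#' Concordance among the three back-to-back replicate measurements of one
#' device application: the OCCC over the n x 3 matrix of replicates with a
#' jackknife confidence interval, plus the three pairwise replicate CCCs.
#' Based on the first measurement triplicate by default. Limb-records with
#' an incomplete triplet are excluded (with a message); more than 20%
#' exclusions is an error.
#'
#' @inheritParams triplicate_mean
#' @param conf_level Confidence level for the jackknife interval.
#' @param jackknife_unit `"limb"` (default) deletes one limb-record per
#'   jackknife step; `"subject"` deletes both limbs of a subject.
#' @return A list of class `"within_set_result"`: `overall` (an
#'   [jackknife_ci()] result for the OCCC), `pairwise` (named list of
#'   pairwise replicate CCC results), `n_units`, `n_excluded`.
#' @export
within_set_agreement <- function(records, device, variant = "raw",
                                 set_index = 1L, conf_level = 0.95,
                                 jackknife_unit = c("limb", "subject")) {
  jackknife_unit <- match.arg(jackknife_unit)
  rm_ <- .replicate_matrix(records, device, variant, set_index)
  groups <- if (jackknife_unit == "subject") rm_$subject else rm_$units
  overall <- jackknife_ci(rm_$m, "occc", conf_level, groups = groups)
  pairs <- utils::combn(3, 2)
  pairwise <- lapply(seq_len(ncol(pairs)), function(i) {
    jackknife_ci(rm_$m[, pairs[, i], drop = FALSE], "ccc", conf_level,
                 groups = groups)
  })
  names(pairwise) <- apply(pairs, 2, function(p) {
    paste0("rep", p[1], "_vs_rep", p[2])
  })
  structure(
    list(device = device, variant = variant, overall = overall,
         pairwise = pairwise, n_units = nrow(rm_$m),
         n_excluded = rm_$n_excluded),
    class = "within_set_result"
  )
}

#' @export
print.within_set_result <- function(x, ...) {
  cat("Within-set agreement:", x$device, "/", x$variant, "\n")
  print(x$overall, ...)
  invisible(x)
}

# paired triplicate means of two extracts, joined on subject x limb
.paired_means <- function(records, device_a, variant_a, set_a,
                          device_b, variant_b, set_b) {
  a <- triplicate_mean(records, device_a, variant_a, set_a)
  b <- triplicate_mean(records, device_b, variant_b, set_b)
  paired <- dplyr::inner_join(
    a, b, by = c("subject_id", "limb"), suffix = c("_a", "_b")
  )
  dropped <- nrow(a) + nrow(b) - 2 * nrow(paired)
  if (dropped > 0) {
    message(dropped, " unpaired limb-record(s) dropped from the comparison.")
  }
  paired
}

#' Agreement of an automated device with the Doppler reference
#'
#' Compares one device's first-triplicate means with the Doppler
#' reference's, per limb-record: pairwise CCC with jackknife CI, bias with
#' a one-sample t-test, and Bland-Altman statistics, for the ABI and
#' separately for the brachial and ankle pressures.
#'
#' @inheritParams within_set_agreement
#' @return A list of class `"vs_doppler_result"` with elements `abi`,
#'   `brachial`, `ankle`, each a list of `agreement` ([jackknife_ci()]),
#'   `bias` ([bias_test()], device minus Doppler) and `bland_altman`;
#'   plus `n_units`.
#' @export
vs_doppler <- function(records, device, variant = "raw", conf_level = 0.95,
                       jackknife_unit = c("limb", "subject")) {
  jackknife_unit <- match.arg(jackknife_unit)
  if (device == "doppler") {
    stop("`device` must be an automated device, not the reference.",
         call. = FALSE)
  }
  paired <- .paired_means(records, device, variant, 1L, "doppler", "raw", 1L)
  if (nrow(paired) < 3L) {
    stop("fewer than 3 paired limb-records for ", device, "/", variant,
         " vs doppler.", call. = FALSE)
  }
  groups <- if (jackknife_unit == "subject") paired$subject_id else
    paste(paired$subject_id, paired$limb, sep = ":")
  one <- function(col) {
    x <- paired[[paste0(col, "_a")]]
    y <- paired[[paste0(col, "_b")]]
    list(
      agreement = jackknife_ci(cbind(device = x, doppler = y), "ccc",
                               conf_level, groups = groups),
      bias = bias_test(x, y),
      bland_altman = bland_altman(x, y, unit_ids = groups)
    )
  }
  structure(
    list(device = device, variant = variant,
         abi = one("abi"), brachial = one("brachial_mmHg"),
         ankle = one("ankle_mmHg"), n_units = nrow(paired)),
    class = "vs_doppler_result"
  )
}

#' @export
print.vs_doppler_result <- function(x, ...) {
  cat("Agreement with Doppler:", x$device, "/", x$variant,
      sprintf("(n = %d limb-records)\n", x$n_units))
  cat("ABI: ")
  print(x$abi$agreement, ...)
  print(x$abi$bias, ...)
  invisible(x)
}

#' Inter- or intra-observer concordance of repeated applications
#'
#' Compares the triplicate means of a device's first and second
#' application. `mode = "inter"` restricts to the series in which the two
#' applications were performed by different observers (series 1-4);
#' `mode = "intra"` to the series with the same observer (series 5-8). The
#' input design is validated against the requested mode. Reports the
#' pairwise CCC with jackknife CI, the bias of the second application
#' relative to the first with a t-test, and the Pearson correlation of the
#' paired means.
#'
#' @inheritParams within_set_agreement
#' @param mode `"intra"` or `"inter"`.
#' @return A list of class `"observer_result"`: `agreement`, `bias`
#'   (second minus first application), `pearson`, `n_units`, `mode`.
#' @export
observer_concordance <- function(records, device, variant = "raw",
                                 mode = c("intra", "inter"),
                                 conf_level = 0.95,
                                 jackknife_unit = c("limb", "subject")) {
  mode <- match.arg(mode)
  jackknife_unit <- match.arg(jackknife_unit)
  if (device == "doppler") {
    stop("observer concordance is defined for the automated devices only ",
         "(the Doppler reference is applied once).", call. = FALSE)
  }
  wanted <- if (mode == "inter") 1:4 else 5:8
  sub <- dplyr::filter(records, .data$series %in% wanted)
  if (nrow(sub) == 0) {
    stop("no records in series ", paste(range(wanted), collapse = "-"),
         " for mode = \"", mode, "\".", call. = FALSE)
  }
  paired <- .paired_means(sub, device, variant, 1L, device, variant, 2L)
  if (nrow(paired) < 3L) {
    stop("fewer than 3 paired limb-records for ", device, "/", variant,
         " (", mode, "-observer).", call. = FALSE)
  }
  same <- paired$observer_a == paired$observer_b
  if (mode == "inter" && any(same)) {
    stop("design violation: same observer for both applications of ",
         device, " in inter-observer series, subjects: ",
         paste(unique(paired$subject_id[same]), collapse = ", "),
         call. = FALSE)
  }
  if (mode == "intra" && any(!same)) {
    stop("design violation: different observers for the applications of ",
         device, " in intra-observer series, subjects: ",
         paste(unique(paired$subject_id[!same]), collapse = ", "),
         call. = FALSE)
  }
  groups <- if (jackknife_unit == "subject") paired$subject_id else
    paste(paired$subject_id, paired$limb, sep = ":")
  structure(
    list(
      device = device, variant = variant, mode = mode,
      agreement = jackknife_ci(
        cbind(first = paired$abi_a, second = paired$abi_b), "ccc",
        conf_level, groups = groups
      ),
      bias = bias_test(paired$abi_b, paired$abi_a),
      bland_altman = bland_altman(paired$abi_b, paired$abi_a,
                                  unit_ids = groups),
      pearson = stats::cor(paired$abi_a, paired$abi_b),
      n_units = nrow(paired)
    ),
    class = "observer_result"
  )
}

#' @export
print.observer_result <- function(x, ...) {
  cat(sprintf("%s-observer concordance: %s / %s (n = %d limb-records)\n",
              x$mode, x$device, x$variant, x$n_units))
  print(x$agreement, ...)
  print(x$bias, ...)
  cat(sprintf("Pearson correlation: %.3f\n", x$pearson))
  invisible(x)
}

#' Run the full agreement analysis of a measurement study
#'
#' Orchestrates, for every automated device/variant present in the data:
#' within-set triplicate agreement (also for the Doppler reference),
#' agreement with Doppler on triplicate means, inter-observer (series 1-4)
#' and intra-observer (series 5-8) concordance, and the same-sample
#' pairwise tests between the two automated devices (difference of their
#' vs-Doppler CCCs, difference of their within-set OCCCs, and the paired
#' comparison of their biases against Doppler).
#'
#' @inheritParams within_set_agreement
#' @param diff_scale Scale of the CCC-difference tests, `"fisher"`
#'   (default) or `"raw"`; see [ccc_difference_test()].
#' @return A list of class `"abi_report"` with elements `within_set`,
#'   `vs_doppler`, `intra_observer`, `inter_observer` (each a named list
#'   keyed by `device/variant`), `pairwise_tests`, and `meta`. P-values are
#'   unadjusted for multiple testing and flagged as suggestive in `meta`.
#' @export
analyze_study <- function(records, conf_level = 0.95,
                          diff_scale = c("fisher", "raw"),
                          jackknife_unit = c("limb", "subject")) {
  diff_scale <- match.arg(diff_scale)
  jackknife_unit <- match.arg(jackknife_unit)
  records <- validate_measurements(records)

  combos <- records |>
    dplyr::distinct(.data$device, .data$variant) |>
    dplyr::arrange(.data$device, .data$variant)
  auto <- combos[combos$device != "doppler", , drop = FALSE]
  key <- function(d, v) paste(d, v, sep = "/")

  within_set <- list()
  for (i in seq_len(nrow(combos))) {
    within_set[[key(combos$device[i], combos$variant[i])]] <-
      within_set_agreement(records, combos$device[i], combos$variant[i],
                           conf_level = conf_level,
                           jackknife_unit = jackknife_unit)
  }
  vs_dop <- list()
  intra <- list()
  inter <- list()
  for (i in seq_len(nrow(auto))) {
    k <- key(auto$device[i], auto$variant[i])
    vs_dop[[k]] <- vs_doppler(records, auto$device[i], auto$variant[i],
                              conf_level, jackknife_unit)
    intra[[k]] <- observer_concordance(records, auto$device[i],
                                       auto$variant[i], "intra",
                                       conf_level, jackknife_unit)
    inter[[k]] <- observer_concordance(records, auto$device[i],
                                       auto$variant[i], "inter",
                                       conf_level, jackknife_unit)
  }

  pairwise_tests <- list()
  devices <- unique(auto$device)
  variants <- unique(auto$variant)
  if (length(devices) == 2) {
    for (v in variants) {
      if (!all(key(devices, v) %in% names(vs_dop))) next
      pairwise_tests[[paste0("vs_doppler_ccc/", v)]] <-
        .vs_doppler_ccc_difference(records, devices[1], devices[2], v,
                                   diff_scale, jackknife_unit)
      pairwise_tests[[paste0("vs_doppler_bias/", v)]] <-
        .vs_doppler_bias_comparison(records, devices[1], devices[2], v)
      pairwise_tests[[paste0("within_set_occc/", v)]] <-
        .within_set_occc_difference(records, devices[1], devices[2], v,
                                    diff_scale, jackknife_unit)
    }
  }

  structure(
    list(
      within_set = within_set, vs_doppler = vs_dop,
      intra_observer = intra, inter_observer = inter,
      pairwise_tests = pairwise_tests,
      meta = list(
        conf_level = conf_level, diff_scale = diff_scale,
        jackknife_unit = jackknife_unit,
        n_records = nrow(records),
        p_value_policy = "unadjusted for multiple testing (suggestive)"
      )
    ),
    class = "abi_report"
  )
}

# CCC(device_a, doppler) vs CCC(device_b, doppler) on the common limbs
.vs_doppler_ccc_difference <- function(records, device_a, device_b, variant,
                                       scale, jackknife_unit) {
  a <- triplicate_mean(records, device_a, variant, 1L)
  b <- triplicate_mean(records, device_b, variant, 1L)
  d <- triplicate_mean(records, "doppler", "raw", 1L)
  joined <- a |>
    dplyr::inner_join(b, by = c("subject_id", "limb"), suffix = c("_a", "_b")) |>
    dplyr::inner_join(
      dplyr::select(d, "subject_id", "limb", abi_dop = "abi"),
      by = c("subject_id", "limb")
    )
  groups <- if (jackknife_unit == "subject") joined$subject_id else NULL
  m <- cbind(a = joined$abi_a, b = joined$abi_b, doppler = joined$abi_dop)
  out <- ccc_difference_test(m, c("a", "doppler"), c("b", "doppler"),
                             scale = scale, groups = groups)
  out$label <- paste0("CCC(", device_a, ", doppler) - CCC(", device_b,
                      ", doppler), variant ", variant)
  out
}

.vs_doppler_bias_comparison <- function(records, device_a, device_b, variant) {
  a <- triplicate_mean(records, device_a, variant, 1L)
  b <- triplicate_mean(records, device_b, variant, 1L)
  d <- triplicate_mean(records, "doppler", "raw", 1L)
  joined <- a |>
    dplyr::inner_join(b, by = c("subject_id", "limb"), suffix = c("_a", "_b")) |>
    dplyr::inner_join(
      dplyr::select(d, "subject_id", "limb", abi_dop = "abi"),
      by = c("subject_id", "limb")
    )
  out <- bias_comparison_test(joined$abi_a - joined$abi_dop,
                              joined$abi_b - joined$abi_dop)
  out$label <- paste0("bias(", device_a, " - doppler) vs bias(", device_b,
                      " - doppler), variant ", variant)
  out
}

# within-set OCCC of device_a's triplet vs device_b's, same limbs
.within_set_occc_difference <- function(records, device_a, device_b, variant,
                                        scale, jackknife_unit) {
  ra <- .replicate_matrix(records, device_a, variant, 1L)
  rb <- .replicate_matrix(records, device_b, variant, 1L)
  common <- intersect(ra$units, rb$units)
  ia <- match(common, ra$units)
  ib <- match(common, rb$units)
  m <- cbind(ra$m[ia, , drop = FALSE], rb$m[ib, , drop = FALSE])
  colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:3))
  groups <- if (jackknife_unit == "subject") ra$subject[ia] else NULL
  out <- ccc_difference_test(m, paste0("a", 1:3), paste0("b", 1:3),
                             scale = scale, groups = groups)
  out$label <- paste0("within-set OCCC(", device_a, ") - OCCC(", device_b,
                      "), variant ", variant)
  out
}

#' @export
print.abi_report <- function(x, ...) {
  cat("ABI agreement analysis report\n")
  cat("  records:", x$meta$n_records,
      "| confidence level:", x$meta$conf_level,
      "| jackknife unit:", x$meta$jackknife_unit, "\n")
  cat("  p-values:", x$meta$p_value_policy, "\n\n")
  cat("Within-set agreement (first triplicate):\n")
  for (k in names(x$within_set)) {
    cat("  ", format(k, width = 28))
    print(x$within_set[[k]]$overall, ...)
  }
  cat("\nAgreement with Doppler (triplicate means):\n")
  for (k in names(x$vs_doppler)) {
    r <- x$vs_doppler[[k]]
    cat("  ", format(k, width = 28))
    cat(sprintf("CCC %.3f; bias %+.3f (p = %.3g)\n",
                r$abi$agreement$estimate, r$abi$bias$mean_difference,
                r$abi$bias$p_value))
  }
  cat("\nObserver concordance (CCC intra / inter):\n")
  for (k in names(x$intra_observer)) {
    cat(sprintf("  %s%.3f / %.3f\n", format(k, width = 30),
                x$intra_observer[[k]]$agreement$estimate,
                x$inter_observer[[k]]$agreement$estimate))
  }
  invisible(x)
}

#' Tabulate observer concordances in the conventional layout
#'
#' Collects the intra- or inter-observer results of an [analyze_study()]
#' report into one row per device/variant with columns CCC, its confidence
#' bounds, bias, bias p-value and Pearson correlation.
#'
#' @param report An `"abi_report"` from [analyze_study()].
#' @param mode `"intra"` or `"inter"`.
#' @return A tibble.
#' @export
concordance_table <- function(report, mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  res <- if (mode == "intra") report$intra_observer else report$inter_observer
  dplyr::bind_rows(lapply(names(res), function(k) {
    r <- res[[k]]
    tibble::tibble(
      method = k,
      ccc = r$agreement$estimate,
      ci_low = r$agreement$ci_low,
      ci_high = r$agreement$ci_high,
      bias = r$bias$mean_difference,
      p_value = r$bias$p_value,
      correlation = r$pearson,
      n = r$n_units
    )
  }))
}
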