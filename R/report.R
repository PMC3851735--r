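# Serialization of an analysis report: machine-readable JSON plus
# human-readable CSV tables and Bland-Altman point files.

.agreement_as_list <- function(a) {
  a[c("estimate", "z_value", "se_z", "ci_low", "ci_high",
      "n_units", "n_columns", "conf_level", "statistic")]
}

.bias_as_list <- function(b) {
  b[c("mean_difference", "sd_difference", "t_statistic", "df",
      "p_value", "n", "loa_low", "loa_high")]
}

.difference_as_list <- function(d) {
  d[c("label", "ccc_a", "ccc_b", "difference", "se_difference",
      "statistic", "p_value", "n_units", "scale")]
}

#' Convert an analysis report to a plain list
#'
#' Flattens an `"abi_report"` into nested base lists suitable for JSON
#' serialization.
#'
#' @param report An `"abi_report"` from [analyze_study()].
#' @return A nested list.
#' @export
report_as_list <- function(report) {
  stopifnot(inherits(report, "abi_report"))
  list(
    meta = report$meta,
    within_set = lapply(report$within_set, function(w) {
      list(overall = .agreement_as_list(w$overall),
           pairwise = lapply(w$pairwise, .agreement_as_list),
           n_units = w$n_units, n_excluded = w$n_excluded)
    }),
    vs_doppler = lapply(report$vs_doppler, function(v) {
      lapply(v[c("abi", "brachial", "ankle")], function(part) {
        list(agreement = .agreement_as_list(part$agreement),
             bias = .bias_as_list(part$bias))
      })
    }),
    intra_observer = lapply(report$intra_observer, function(o) {
      list(agreement = .agreement_as_list(o$agreement),
           bias = .bias_as_list(o$bias), pearson = o$pearson,
           n_units = o$n_units)
    }),
    inter_observer = lapply(report$inter_observer, function(o) {
      list(agreement = .agreement_as_list(o$agreement),
           bias = .bias_as_list(o$bias), pearson = o$pearson,
           n_units = o$n_units)
    }),
    pairwise_tests = lapply(report$pairwise_tests, .difference_as_list)
  )
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (the full machine-readable report),
#' `intra_observer.csv` / `inter_observer.csv` (concordance tables in the
#' conventional one-row-per-method layout) and one Bland-Altman point file
#' per device/variant comparison with Doppler.
#'
#' @param report An `"abi_report"` from [analyze_study()].
#' @param dir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "abi_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_as_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(concordance_table(report, "intra"),
                   file.path(dir, "intra_observer.csv"))
  readr::write_csv(concordance_table(report, "inter"),
                   file.path(dir, "inter_observer.csv"))
  for (k in names(report$vs_doppler)) {
    ba <- report$vs_doppler[[k]]$abi$bland_altman
    fname <- paste0("bland_altman_", gsub("/", "_", k), ".csv")
    readr::write_csv(ba$data, file.path(dir, fname))
  }
  invisible(dir)
}
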