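# Feasibility summaries: subject acceptance scores (discrete 1 = worst to
# 5 = best) and assessment durations, compared between the two automated
# devices with the paired Wilcoxon signed-rank test.

# paired Wilcoxon with zero differences dropped (Wilcoxon's original
# policy); exact distribution attempted below 20 informative pairs,
# normal approximation with continuity correction otherwise.
.wilcoxon_paired_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  use_exact <- length(d) < 20
  suppressWarnings(
    stats::wilcox.test(d, exact = use_exact, correct = TRUE)$p.value
  )
}

#' Feasibility statistics for two automated devices
#'
#' Summarises subject acceptance scores (means) and assessment durations
#' (medians with interquartile range) for two devices measured on the same
#' subjects, and compares the devices with paired Wilcoxon signed-rank
#' tests. Pairs with zero difference are dropped before the test; if all
#' pairs are tied the p-value is 1.
#'
#' @param scores_a,scores_b Paired integer vectors of acceptance scores in
#'   1 (worst) to 5 (best), one per subject.
#' @param durations_a,durations_b Optional paired numeric vectors of
#'   assessment durations in minutes.
#' @param labels Character vector of length 2 naming the devices.
#' @return A list of class `"feasibility_result"`: `scores` (tibble of
#'   device, n, mean_score), `score_p_value`, and when durations are given
#'   `durations` (tibble of device, median, iqr_low, iqr_high) and
#'   `duration_p_value`.
#' @examples
#' feasibility_stats(rep(1:5, c(2, 5, 2, 12, 35)),
#'                   rep(1:5, c(2, 3, 3, 13, 35)))
#' @export
feasibility_stats <- function(scores_a, scores_b,
                              durations_a = NULL, durations_b = NULL,
                              labels = c("device_a", "device_b")) {
  check_scores <- function(s, nm) {
    if (anyNA(s) || any(s != round(s)) || any(s < 1 | s > 5)) {
      stop("`", nm, "` must be integer scores in 1..5.", call. = FALSE)
    }
  }
  check_scores(scores_a, "scores_a")
  check_scores(scores_b, "scores_b")
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors must be paired (equal length).", call. = FALSE)
  }
  out <- list(
    scores = tibble::tibble(
      device = labels,
      n = c(length(scores_a), length(scores_b)),
      mean_score = c(mean(scores_a), mean(scores_b))
    ),
    score_p_value = .wilcoxon_paired_p(scores_a, scores_b)
  )
  if (!is.null(durations_a) || !is.null(durations_b)) {
    if (is.null(durations_a) || is.null(durations_b) ||
        length(durations_a) != length(durations_b)) {
      stop("durations must be given for both devices and paired.",
           call. = FALSE)
    }
    qa <- stats::quantile(durations_a, c(0.25, 0.75), names = FALSE)
    qb <- stats::quantile(durations_b, c(0.25, 0.75), names = FALSE)
    out$durations <- tibble::tibble(
      device = labels,
      median = c(stats::median(durations_a), stats::median(durations_b)),
      iqr_low = c(qa[1], qb[1]),
      iqr_high = c(qa[2], qb[2])
    )
    out$duration_p_value <- .wilcoxon_paired_p(durations_a, durations_b)
  }
  structure(out, class = "feasibility_result")
}

#' @export
print.feasibility_result <- function(x, ...) {
  cat("Acceptance scores (1 = worst, 5 = best):\n")
  for (i in seq_len(nrow(x$scores))) {
    cat(sprintf("  %s: mean %.2f (n = %d)\n", x$scores$device[i],
                x$scores$mean_score[i], x$scores$n[i]))
  }
  cat(sprintf("  paired Wilcoxon p = %.3g\n", x$score_p_value))
  if (!is.null(x$durations)) {
    cat("Durations (minutes):\n")
    for (i in seq_len(nrow(x$durations))) {
      cat(sprintf("  %s: median %.0f (IQR %.0f-%.0f)\n",
                  x$durations$device[i], x$durations$median[i],
                  x$durations$iqr_low[i], x$durations$iqr_high[i]))
    }
    cat(sprintf("  paired Wilcoxon p = %.3g\n", x$duration_p_value))
  }
  invisible(x)
}
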