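# Bias estimation for paired measurements: arithmetic mean of paired
# differences, one-sample t-test, Bland-Altman 95% limits of agreement
# (mean difference +/- 1.96 sd, sample sd with n-1 denominator).

.new_bias_result <- function(d, n) {
  md <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    # all differences identical: a zero mean is exact agreement, a nonzero
    # mean is a bias established with certainty under the t model
    t_stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    t_stat <- md / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(
    list(
      mean_difference = md, sd_difference = sd_d,
      t_statistic = t_stat, df = n - 1, p_value = p, n = n,
      loa_low = md - 1.96 * sd_d, loa_high = md + 1.96 * sd_d
    ),
    class = "bias_result"
  )
}

.check_paired <- function(x, y, what = c("x", "y")) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`", what[1], "` and `", what[2], "` must have the same length.",
         call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("at least 2 paired observations are required.", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("missing values are not allowed.", call. = FALSE)
  }
  list(x = x, y = y)
}

#' Bias of paired measurements (one-sample t-test)
#'
#' Estimates the bias of method `x` relative to method `y` as the
#' arithmetic mean of the paired differences \eqn{x - y}, tests it against
#' zero with a two-sided one-sample t-test (n - 1 degrees of freedom), and
#' reports Bland-Altman 95% limits of agreement
#' \eqn{\bar d \pm 1.96\, s_d}.
#'
#' @param x,y Paired numeric vectors (same units, e.g. both ABI or both
#'   mmHg), equal length \eqn{\ge 2}, no missing values.
#' @return An object of class `"bias_result"`: a list with
#'   `mean_difference`, `sd_difference`, `t_statistic`, `df`, `p_value`,
#'   `n`, `loa_low`, `loa_high`.
#' @examples
#' bias_test(c(1.15, 1.22, 1.08, 1.30), c(1.10, 1.18, 1.05, 1.21))
#' @export
bias_test <- function(x, y) {
  p <- .check_paired(x, y)
  .new_bias_result(p$x - p$y, length(p$x))
}

#' Compare the biases of two methods against a common reference
#'
#' Given per-unit difference vectors of two methods against the same
#' reference (e.g. device A minus Doppler and device B minus Doppler on
#' the same limbs), performs a paired two-sided t-test of
#' `diff_a - diff_b`. Equivalent to `bias_test(diff_a, diff_b)`; provided
#' as a named operation because comparing biases is a distinct scientific
#' question from estimating one.
#'
#' @param diff_a,diff_b Paired numeric vectors of individual differences,
#'   aligned on the same units.
#' @return A `"bias_result"` whose `mean_difference` is the mean of
#'   `diff_a - diff_b`.
#' @examples
#' bias_comparison_test(c(0.04, 0.06, 0.05), c(0.12, 0.15, 0.11))
#' @export
bias_comparison_test <- function(diff_a, diff_b) {
  p <- .check_paired(diff_a, diff_b, c("diff_a", "diff_b"))
  .new_bias_result(p$x - p$y, length(p$x))
}

#' Bland-Altman statistics for paired measurements
#'
#' Returns the per-unit (mean, difference) pairs underlying a Bland-Altman
#' plot together with the mean bias and 95% limits of agreement. This is
#' the computation layer only; see [plot_bland_altman()] for the display.
#'
#' @inheritParams bias_test
#' @param unit_ids Optional identifiers for the pairs (defaults to
#'   `1:n`), carried into the output table.
#' @return An object of class `"bland_altman"`: a list with `data` (a
#'   tibble of `unit_id`, `mean`, `difference`) and `bias` (the
#'   [bias_test()] result for `x` vs `y`).
#' @examples
#' ba <- bland_altman(c(1.15, 1.22, 1.08), c(1.10, 1.18, 1.05))
#' ba$bias
#' @export
bland_altman <- function(x, y, unit_ids = NULL) {
  p <- .check_paired(x, y)
  n <- length(p$x)
  if (is.null(unit_ids)) unit_ids <- seq_len(n)
  if (length(unit_ids) != n) {
    stop("`unit_ids` must match the number of pairs.", call. = FALSE)
  }
  structure(
    list(
      data = tibble::tibble(
        unit_id = unit_ids,
        mean = (p$x + p$y) / 2,
        difference = p$x - p$y
      ),
      bias = .new_bias_result(p$x - p$y, n)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bias_result <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Bias %+.*f (sd %.*f, n = %d), t = %.3g, p = %.3g; 95%% LoA [%.*f, %.*f]\n",
    digits, x$mean_difference, digits, x$sd_difference, x$n,
    x$t_statistic, x$p_value, digits, x$loa_low, digits, x$loa_high
  ))
  invisible(x)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman analysis of", nrow(x$data), "pairs\n")
  print(x$bias, ...)
  invisible(x)
}

#' Bland-Altman plot
#'
#' Draws the conventional Bland-Altman display: paired differences against
#' paired means with horizontal lines at the mean bias and the 95% limits
#' of agreement.
#'
#' @param ba A `"bland_altman"` object from [bland_altman()].
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, xlab = "Mean of methods",
                              ylab = "Difference between methods") {
  stopifnot(inherits(ba, "bland_altman"))
  b <- ba$bias
  ggplot2::ggplot(ba$data, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = b$mean_difference, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(b$loa_low, b$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}
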