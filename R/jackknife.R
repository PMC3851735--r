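# Leave-one-out (jackknife) inference for concordance statistics on the
# Fisher z scale, using the pseudovalue construction
#   z_i = g * z - (g - 1) * z_(-i),   SE = sd(z_i) / sqrt(g),
# with g the number of deletion units.

.check_matrix <- function(m, min_rows = 3L) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    stop("missing cells are not allowed; build a complete-case matrix first.",
         call. = FALSE)
  }
  if (ncol(m) < 2L) stop("`m` needs at least 2 columns.", call. = FALSE)
  if (nrow(m) < min_rows) {
    stop("`m` needs at least ", min_rows, " rows.", call. = FALSE)
  }
  m
}

.resolve_groups <- function(groups, n) {
  if (is.null(groups)) groups <- seq_len(n)
  if (length(groups) != n) {
    stop("`groups` must have one entry per row of `m`.", call. = FALSE)
  }
  groups
}

# evaluate `stat` on every leave-one-group-out subsample; abort with the
# offending unit on a degenerate subsample (silently skipping would bias
# the SE).
.jackknife_values <- function(m, groups, stat) {
  units <- unique(groups)
  vapply(units, function(u) {
    sub <- m[groups != u, , drop = FALSE]
    tryCatch(
      stat(sub),
      error = function(e) {
        stop("degenerate leave-one-out resample when deleting unit '", u,
             "': ", conditionMessage(e), call. = FALSE)
      }
    )
  }, numeric(1))
}

#' Jackknife confidence interval for a CCC or OCCC
#'
#' Estimates a concordance correlation coefficient (pairwise CCC for two
#' columns, OCCC for any number of columns) and attaches a leave-one-out
#' jackknife standard error and confidence interval computed on the Fisher
#' z scale. The statistic is evaluated on the full sample and on each of
#' the g leave-one-unit-out subsamples; pseudovalues
#' \eqn{\hat z_i = g z - (g-1) z_{(-i)}} give
#' \eqn{\mathrm{SE} = \mathrm{sd}(\hat z_i)/\sqrt{g}}, and the interval is
#' \eqn{\tanh(z \pm q \cdot \mathrm{SE})} with \eqn{q} the standard-normal
#' quantile.
#'
#' @param m Numeric matrix, n units (rows) by J measurements (columns),
#'   complete cases, \eqn{n \ge 3}.
#' @param statistic `"occc"` (default; any \eqn{J \ge 2}) or `"ccc"`
#'   (requires exactly 2 columns). The two coincide for \eqn{J = 2}.
#' @param conf_level Confidence level, default `0.95`.
#' @param groups Optional vector (length n) of deletion-unit identifiers.
#'   By default every row is its own jackknife unit (one limb-level record,
#'   limbs being treated as independent); passing e.g. subject identifiers
#'   deletes both limbs of a subject at once for sensitivity analysis.
#' @return An object of class `"agreement_result"`: a list with elements
#'   `estimate`, `z_value`, `se_z`, `ci_low`, `ci_high`, `n_units`,
#'   `n_columns`, `conf_level`, `statistic`.
#' @examples
#' set.seed(1)
#' truth <- rnorm(30, 1.1, 0.1)
#' m <- cbind(truth + rnorm(30, 0, 0.05), truth + rnorm(30, 0, 0.05))
#' jackknife_ci(m)
#' @export
jackknife_ci <- function(m, statistic = c("occc", "ccc"), conf_level = 0.95,
                         groups = NULL) {
  statistic <- match.arg(statistic)
  m <- .check_matrix(m)
  if (statistic == "ccc" && ncol(m) != 2L) {
    stop('statistic = "ccc" requires exactly 2 columns.', call. = FALSE)
  }
  if (!is.numeric(conf_level) || conf_level <= 0 || conf_level >= 1) {
    stop("`conf_level` must be in (0, 1).", call. = FALSE)
  }
  groups <- .resolve_groups(groups, nrow(m))
  g <- length(unique(groups))
  if (g < 3L) stop("at least 3 jackknife units are required.", call. = FALSE)

  est <- occc(m)  # identical to ccc() for J = 2
  full <- .fisher_quiet(est)
  loo <- .fisher_quiet(.jackknife_values(m, groups, occc))
  if (full$clamped || loo$clamped) {
    warning("CCC within 1e-12 of +/-1 in full sample or a jackknife ",
            "resample; clamped before the Fisher transform.", call. = FALSE)
  }
  pseudo <- g * full$z - (g - 1) * loo$z
  se_z <- stats::sd(pseudo) / sqrt(g)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_low <- tanh(full$z - q * se_z)
  ci_high <- tanh(full$z + q * se_z)
  # clamping can leave tanh(z) a hair below a raw estimate of exactly 1;
  # the interval always contains the point estimate
  ci_low <- min(ci_low, est)
  ci_high <- max(ci_high, est)

  structure(
    list(
      estimate = est, z_value = full$z, se_z = se_z,
      ci_low = ci_low, ci_high = ci_high,
      n_units = g, n_columns = ncol(m),
      conf_level = conf_level, statistic = statistic
    ),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, digits = 3, ...) {
  lab <- if (x$n_columns > 2L) "OCCC" else "CCC"
  cat(sprintf(
    "%s %.*f; %d%%-CI %.*f-%.*f (jackknife, n = %d units, J = %d)\n",
    lab, digits, x$estimate, round(100 * x$conf_level),
    digits, x$ci_low, digits, x$ci_high, x$n_units, x$n_columns
  ))
  invisible(x)
}

#' Same-sample jackknife test for the difference of two CCCs
#'
#' Tests whether two concordance coefficients computed on the same sampling
#' units differ, e.g. the CCC of each automated device against the same
#' Doppler reference, or the within-set OCCC of one device's triplicate
#' against another's. Overlapping column sets are permitted. Per
#' leave-one-out subsample the difference \eqn{d_{(-i)} = z_{A,(-i)} -
#' z_{B,(-i)}} is formed (Fisher scale by default), the pseudovalue SE is
#' computed as in [jackknife_ci()], and a two-sided p-value is taken from
#' the standard normal distribution of \eqn{d/\mathrm{SE}(d)}.
#'
#' @inheritParams jackknife_ci
#' @param cols_a,cols_b Column indices or names of `m` selecting the two
#'   statistics: 2 columns give a pairwise CCC, more give an OCCC.
#' @param scale `"fisher"` (default) takes the difference of the
#'   Fisher-transformed coefficients, consistent with the CI construction;
#'   `"raw"` differences the coefficients directly.
#' @return An object of class `"ccc_difference"`: a list with `ccc_a`,
#'   `ccc_b`, `difference` (on the chosen scale), `se_difference`,
#'   `statistic`, `p_value`, `n_units`, `scale`.
#' @examples
#' set.seed(1)
#' ref <- rnorm(40, 1.1, 0.1)
#' m <- cbind(ref = ref, a = ref + rnorm(40, 0, 0.03),
#'            b = ref + rnorm(40, 0, 0.08))
#' ccc_difference_test(m, c("a", "ref"), c("b", "ref"))
#' @export
ccc_difference_test <- function(m, cols_a, cols_b,
                                scale = c("fisher", "raw"), groups = NULL) {
  scale <- match.arg(scale)
  m <- .check_matrix(m)
  a <- m[, cols_a, drop = FALSE]
  b <- m[, cols_b, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) {
    stop("`cols_a` and `cols_b` must each select at least 2 columns.",
         call. = FALSE)
  }
  groups <- .resolve_groups(groups, nrow(m))
  g <- length(unique(groups))
  if (g < 3L) stop("at least 3 jackknife units are required.", call. = FALSE)

  trans <- if (scale == "fisher") function(r) .fisher_quiet(r)$z else identity
  diff_stat <- function(mm) {
    trans(occc(mm[, cols_a, drop = FALSE])) -
      trans(occc(mm[, cols_b, drop = FALSE]))
  }
  ccc_a <- occc(a)
  ccc_b <- occc(b)
  d_full <- diff_stat(m)
  d_loo <- .jackknife_values(m, groups, diff_stat)
  pseudo <- g * d_full - (g - 1) * d_loo
  se_d <- stats::sd(pseudo) / sqrt(g)

  if (se_d == 0) {
    # identical column sets (or perfectly rigid difference): no sampling
    # variability of the contrast
    stat <- if (d_full == 0) 0 else sign(d_full) * Inf
    p <- if (d_full == 0) 1 else 0
  } else {
    stat <- d_full / se_d
    p <- 2 * stats::pnorm(-abs(stat))
  }

  structure(
    list(
      ccc_a = ccc_a, ccc_b = ccc_b,
      difference = d_full, se_difference = se_d,
      statistic = stat, p_value = p,
      n_units = g, scale = scale
    ),
    class = "ccc_difference"
  )
}

#' @export
print.ccc_difference <- function(x, digits = 3, ...) {
  cat(sprintf(
    paste0("CCC difference (%s scale): A = %.*f, B = %.*f, d = %.*f ",
           "(SE %.*f), p = %.3g [jackknife, n = %d units]\n"),
    x$scale, digits, x$ccc_a, digits, x$ccc_b, digits, x$difference,
    digits, x$se_difference, x$p_value, x$n_units
  ))
  invisible(x)
}
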