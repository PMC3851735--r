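# Moment-based concordance estimators. All second moments use the 1/n
# (biased) convention of Lin's original estimator; applied consistently the
# convention cancels from the CCC ratio.

#' Lin's concordance correlation coefficient
#'
#' Computes Lin's concordance correlation coefficient (CCC) between two
#' paired measurement vectors,
#' \deqn{\hat\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},}
#' where variances and the covariance use the \eqn{1/n} moment convention.
#' The CCC combines precision (Pearson correlation) and accuracy (closeness
#' of the means and variances): it equals 1 only for perfect agreement on
#' the identity line, and satisfies \eqn{|\hat\rho_c| \le |r|}.
#'
#' @param x,y Numeric vectors of equal length (at least 2), no missing
#'   values. Units are arbitrary but must match (e.g. both ABI, both mmHg).
#' @return A single number in \eqn{[-1, 1]}.
#' @seealso [occc()] for more than two measurement columns, [jackknife_ci()]
#'   for confidence intervals.
#' @examples
#' ccc(c(1, 2, 3, 4), c(1.1, 2.1, 3.1, 4.1))
#' @export
ccc <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length (", length(x), " vs ",
         length(y), ").", call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("at least 2 paired observations are required.", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("missing values are not allowed; build a complete-case matrix first.",
         call. = FALSE)
  }
  mx <- mean(x)
  my <- mean(y)
  sxx <- mean((x - mx)^2)
  syy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sxx + syy + (mx - my)^2
  if (denom == 0) {
    stop("CCC is undefined: both samples are constant with equal means.",
         call. = FALSE)
  }
  2 * sxy / denom
}

#' Overall concordance correlation coefficient (OCCC)
#'
#' Generalizes Lin's CCC to \eqn{J \ge 2} measurement columns:
#' \deqn{\mathrm{OCCC} = \frac{2 \sum_{j<k} s_{jk}}
#'   {\sum_{j<k} \left(s_j^2 + s_k^2 + (\bar x_j - \bar x_k)^2\right)},}
#' a weighted mean of all pairwise CCCs with weights equal to the pairwise
#' denominators. For \eqn{J = 2} it reduces exactly to [ccc()]; it is
#' invariant under permutation of the columns.
#'
#' @param m Numeric matrix (or data frame) with n rows (units) and
#'   \eqn{J \ge 2} columns (measurements), no missing cells.
#' @return A single number in \eqn{[-1, 1]}.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(1.1, 1.9, 3.2), c = c(0.9, 2.2, 2.8))
#' occc(m)
#' @export
occc <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  n <- nrow(m)
  J <- ncol(m)
  if (J < 2L) stop("`m` needs at least 2 columns.", call. = FALSE)
  if (n < 2L) stop("`m` needs at least 2 rows.", call. = FALSE)
  if (anyNA(m)) {
    stop("missing values are not allowed; build a complete-case matrix first.",
         call. = FALSE)
  }
  mu <- colMeans(m)
  cm <- sweep(m, 2L, mu)
  # explicit per-pair sums (not crossprod): identical columns then yield
  # bitwise-identical variance and covariance terms, so perfect agreement
  # returns exactly 1
  sv <- vapply(seq_len(J), function(j) sum(cm[, j] * cm[, j]) / n, numeric(1))
  num <- 0
  den <- 0
  for (j in seq_len(J - 1L)) {
    for (k in (j + 1L):J) {
      sjk <- sum(cm[, j] * cm[, k]) / n
      pair_den <- sv[j] + sv[k] + (mu[j] - mu[k])^2
      num <- num + 2 * sjk
      den <- den + pair_den
    }
  }
  if (den == 0) {
    stop("OCCC is undefined: all columns are constant with equal means.",
         call. = FALSE)
  }
  unname(num / den)
}

#' Fisher z-transformation and its inverse
#'
#' `fisher_z()` maps a correlation-like statistic to the approximately
#' normal z scale via \code{atanh}; `inverse_fisher()` maps back via
#' \code{tanh}. Values within `1e-12` of \eqn{\pm 1} are clamped to
#' \eqn{\pm(1 - 10^{-12})} with a warning, so that jackknife resamples of
#' near-perfect data do not produce infinities; values beyond \eqn{[-1, 1]}
#' are a domain error.
#'
#' @param r Numeric vector of correlations/CCCs in \eqn{[-1, 1]}.
#' @param z Numeric vector on the Fisher z scale.
#' @return Numeric vector of the same length.
#' @examples
#' fisher_z(0.88)
#' inverse_fisher(fisher_z(0.49))
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1)) {
    stop("fisher_z is undefined outside [-1, 1].", call. = FALSE)
  }
  clamp <- abs(r) > 1 - 1e-12
  if (any(clamp)) {
    warning("|r| within 1e-12 of 1; clamped before atanh.", call. = FALSE)
    r[clamp] <- sign(r[clamp]) * (1 - 1e-12)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher <- function(z) {
  tanh(z)
}

# clamped atanh without the per-call warning; jackknife loops report one
# warning for the whole resampling pass instead.
.fisher_quiet <- function(r) {
  clamped <- abs(r) > 1 - 1e-12
  r[clamped] <- sign(r[clamped]) * (1 - 1e-12)
  list(z = atanh(r), clamped = any(clamped))
}
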