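# Independent brute-force oracles, deliberately written without sharing any
# code path with the package: explicit sums, literal leave-one-out loops.

oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxx <- sum((x - mx) * (x - mx)) / n
  syy <- sum((y - my) * (y - my)) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sxx + syy + (mx - my) * (mx - my))
}

oracle_occc <- function(m) {
  J <- ncol(m)
  num <- 0
  den <- 0
  for (j in 1:(J - 1)) {
    for (k in (j + 1):J) {
      mj <- sum(m[, j]) / nrow(m)
      mk <- sum(m[, k]) / nrow(m)
      sj <- sum((m[, j] - mj)^2) / nrow(m)
      sk <- sum((m[, k] - mk)^2) / nrow(m)
      sjk <- sum((m[, j] - mj) * (m[, k] - mk)) / nrow(m)
      num <- num + 2 * sjk
      den <- den + sj + sk + (mj - mk)^2
    }
  }
  num / den
}

# weighted mean of pairwise CCCs with pairwise-denominator weights
oracle_occc_weighted <- function(m) {
  J <- ncol(m)
  cccs <- c()
  w <- c()
  for (j in 1:(J - 1)) {
    for (k in (j + 1):J) {
      mj <- sum(m[, j]) / nrow(m)
      mk <- sum(m[, k]) / nrow(m)
      sj <- sum((m[, j] - mj)^2) / nrow(m)
      sk <- sum((m[, k] - mk)^2) / nrow(m)
      cccs <- c(cccs, oracle_ccc(m[, j], m[, k]))
      w <- c(w, sj + sk + (mj - mk)^2)
    }
  }
  sum(w * cccs) / sum(w)
}

# literal leave-one-out pseudovalue SE on the Fisher scale, recomputing the
# statistic n times; same clamping policy as the package
oracle_atanh <- function(r) {
  if (abs(r) > 1 - 1e-12) r <- sign(r) * (1 - 1e-12)
  0.5 * log((1 + r) / (1 - r))
}

oracle_jackknife_se <- function(m, stat, groups = seq_len(nrow(m))) {
  units <- unique(groups)
  g <- length(units)
  z_full <- oracle_atanh(stat(m))
  pseudo <- numeric(g)
  for (i in seq_len(g)) {
    z_i <- oracle_atanh(stat(m[groups != units[i], , drop = FALSE]))
    pseudo[i] <- g * z_full - (g - 1) * z_i
  }
  sqrt(sum((pseudo - mean(pseudo))^2) / (g - 1)) / sqrt(g)
}

# bivariate normal sample with given moments
rbvn <- function(n, mu1, mu2, s1, s2, rho) {
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  cbind(mu1 + s1 * z1, mu2 + s2 * (rho * z1 + sqrt(1 - rho^2) * z2))
}

# population CCC of that bivariate normal
pop_ccc_bvn <- function(mu1, mu2, s1, s2, rho) {
  2 * rho * s1 * s2 / (s1^2 + s2^2 + (mu1 - mu2)^2)
}

# small random matrix with occasional near-collinear columns
random_matrix <- function(n, J) {
  base <- rnorm(n)
  m <- sapply(seq_len(J), function(j) {
    base * runif(1, 0.5, 1.5) + rnorm(n, sd = runif(1, 0.2, 1)) + rnorm(1)
  })
  matrix(m, nrow = n)
}
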