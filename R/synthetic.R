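# Synthetic multi-device, multi-observer ABI study generator.
#
# Generative model (pressure scale, mmHg): each subject has a true right-arm
# brachial systolic pressure B ~ N(brachial_mean, brachial_sd^2) and per-limb
# true ABI T (bivariate normal across limbs with correlation
# `limb_correlation`, truncated to (0.3, 1.6)); the true ankle pressure of a
# limb is T * B. A measured pressure adds, on the pressure scale: a
# device-and-site-specific systematic bias, a fixed second-application drop,
# a per (observer, device, site) random offset, and independent replicate
# noise. ABI is always the ratio of the measured ankle to the measured
# brachial pressure; both limbs share the single brachial measurement of an
# application, and each application yields a replicate triplet.

.DEVICES <- c("doppler", "vicorder", "vascular_explorer")
.ABI_TRUNC <- c(0.3, 1.6)

# E[f(B) / (B + shift + eta)] with B ~ N(mean, sd^2) integrated numerically
# and eta (pressure noise + observer offset) ~ N(0, noise_var) handled to
# second order; used to calibrate device biases to a target ABI inflation.
.einv_denominator <- function(f, shift, brachial_mean, brachial_sd,
                              noise_var) {
  integrand <- function(B) {
    m <- B + shift
    stats::dnorm(B, brachial_mean, brachial_sd) * f(B) *
      (1 / m) * (1 + noise_var / m^2)
  }
  stats::integrate(integrand,
                   brachial_mean - 6.5 * brachial_sd,
                   brachial_mean + 6.5 * brachial_sd,
                   rel.tol = 1e-10)$value
}

# brachial bias b solving E[ABI_device] - E[ABI_reference] = target, where
# ABI = T B / (B + b + eta); the reference has b = 0
.calibrate_brachial_bias <- function(target, true_abi_mean, brachial_mean,
                                     brachial_sd, noise_var) {
  ref <- .einv_denominator(identity, 0, brachial_mean, brachial_sd, noise_var)
  # keep the search inside the region where B + b stays positive over the
  # integration range, away from the 1/(B + b) pole
  lim <- 0.9 * (brachial_mean - 6.5 * brachial_sd)
  if (lim <= 0) {
    stop("brachial_sd too large relative to brachial_mean for bias ",
         "calibration.", call. = FALSE)
  }
  stats::uniroot(function(b) {
    true_abi_mean *
      (.einv_denominator(identity, b, brachial_mean, brachial_sd, noise_var) -
         ref) - target
  }, interval = c(-lim, lim), tol = 1e-10)$root
}

# ankle bias a solving a * E[1 / (B + eta)] = target (mean ABI inflation)
.calibrate_ankle_bias <- function(target, brachial_mean, brachial_sd,
                                  noise_var) {
  target / .einv_denominator(function(B) 1, 0, brachial_mean, brachial_sd,
                             noise_var)
}

#' Configuration of the synthetic ABI study
#'
#' Builds and validates the parameter set for [generate_study()]. The
#' defaults emulate a 56-subject, 8-series repeated-measures design in which
#' a handheld Doppler reference is applied once (one replicate triplet) and
#' two automated photo-plethysmography devices are each applied twice, with
#' series 1-4 assigning the two applications to different observers
#' (inter-observer design) and series 5-8 to the same observer
#' (intra-observer design).
#'
#' The default device biases are calibrated on the pressure scale (by
#' numerically inverting the model-implied expectation) so that the mean
#' ABI inflation relative to Doppler is +0.05 for the deflation-based
#' device (a negative brachial bias, `vicorder`) and +0.13 for the
#' inflation-based device (a positive ankle bias, `vascular_explorer`).
#'
#' @param n_subjects Number of subjects (default 56). Must equal
#'   `sum(series_sizes)`.
#' @param series_sizes Integer vector of length 8: subjects per series
#'   (default 7 each).
#' @param true_abi_mean,true_abi_sd Mean and SD of the true per-limb ABI
#'   (unitless; defaults 1.10 and 0.10), truncated to (0.3, 1.6).
#' @param brachial_mean,brachial_sd Mean and SD of the true brachial
#'   systolic pressure in mmHg (defaults 130 and 15).
#' @param device_brachial_bias,device_ankle_bias Named numeric vectors
#'   (names `doppler`, `vicorder`, `vascular_explorer`) of systematic
#'   pressure biases in mmHg at each site. `NULL` (the default) calibrates
#'   the vicorder brachial bias and the vascular_explorer ankle bias to
#'   the +0.05 / +0.13 mean ABI inflations, all other entries zero.
#' @param replicate_noise_sd SD in mmHg of independent measurement noise
#'   added to every recorded pressure (default 4).
#' @param observer_effect_sd SD in mmHg of the random offset drawn once per
#'   (observer, device, site) combination (default 2).
#' @param second_set_drop Named list (per automated device) of length-2
#'   numeric vectors `c(brachial = , ankle = )`: the fixed systematic
#'   pressure change of the second application relative to the first, in
#'   mmHg. Defaults: vicorder -5.2 / -7.5, vascular_explorer -4.6 / -4.4.
#' @param limb_correlation Within-subject correlation of true ABI across
#'   limbs, in \[0, 1) (default 0.6).
#' @param seed Integer RNG seed recorded in the configuration and used by
#'   [generate_study()] (default 1).
#' @return A validated list of class `"synthetic_config"`.
#' @examples
#' cfg <- synthetic_config(seed = 42)
#' cfg$device_ankle_bias
#' @export
synthetic_config <- function(n_subjects = 56L,
                             series_sizes = rep(7L, 8L),
                             true_abi_mean = 1.10,
                             true_abi_sd = 0.10,
                             brachial_mean = 130,
                             brachial_sd = 15,
                             device_brachial_bias = NULL,
                             device_ankle_bias = NULL,
                             replicate_noise_sd = 4,
                             observer_effect_sd = 2,
                             second_set_drop = list(
                               vicorder = c(brachial = -5.2, ankle = -7.5),
                               vascular_explorer = c(brachial = -4.6, ankle = -4.4)
                             ),
                             limb_correlation = 0.6,
                             seed = 1L) {
  noise_var <- replicate_noise_sd^2 + observer_effect_sd^2
  if (is.null(device_brachial_bias)) {
    device_brachial_bias <- c(
      doppler = 0,
      vicorder = .calibrate_brachial_bias(0.05, true_abi_mean, brachial_mean,
                                          brachial_sd, noise_var),
      vascular_explorer = 0
    )
  }
  if (is.null(device_ankle_bias)) {
    device_ankle_bias <- c(
      doppler = 0,
      vicorder = 0,
      vascular_explorer = .calibrate_ankle_bias(0.13, brachial_mean,
                                                brachial_sd, noise_var)
    )
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    series_sizes = as.integer(series_sizes),
    true_abi_mean = true_abi_mean, true_abi_sd = true_abi_sd,
    brachial_mean = brachial_mean, brachial_sd = brachial_sd,
    device_brachial_bias = device_brachial_bias,
    device_ankle_bias = device_ankle_bias,
    replicate_noise_sd = replicate_noise_sd,
    observer_effect_sd = observer_effect_sd,
    second_set_drop = second_set_drop,
    limb_correlation = limb_correlation,
    seed = as.integer(seed)
  )
  problems <- character()
  if (length(cfg$series_sizes) != 8L || any(cfg$series_sizes < 1L)) {
    problems <- c(problems, "`series_sizes` must be 8 positive integers")
  }
  if (cfg$n_subjects != sum(cfg$series_sizes)) {
    problems <- c(problems, "`n_subjects` must equal sum(series_sizes)")
  }
  for (nm in c("true_abi_sd", "brachial_sd", "replicate_noise_sd",
               "observer_effect_sd")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0) {
      problems <- c(problems, paste0("`", nm, "` must be >= 0"))
    }
  }
  if (cfg$true_abi_mean <= .ABI_TRUNC[1] || cfg$true_abi_mean >= .ABI_TRUNC[2]) {
    problems <- c(problems, "`true_abi_mean` must lie inside (0.3, 1.6)")
  }
  if (cfg$brachial_mean <= 0) {
    problems <- c(problems, "`brachial_mean` must be positive")
  }
  for (nm in c("device_brachial_bias", "device_ankle_bias")) {
    if (!all(.DEVICES %in% names(cfg[[nm]]))) {
      problems <- c(problems,
                    paste0("`", nm, "` must name all of: ",
                           paste(.DEVICES, collapse = ", ")))
    }
  }
  auto <- setdiff(.DEVICES, "doppler")
  if (!all(auto %in% names(cfg$second_set_drop)) ||
      !all(vapply(cfg$second_set_drop,
                  function(v) all(c("brachial", "ankle") %in% names(v)),
                  logical(1)))) {
    problems <- c(problems,
                  "`second_set_drop` must give c(brachial=, ankle=) per automated device")
  }
  if (!is.numeric(cfg$limb_correlation) || cfg$limb_correlation < 0 ||
      cfg$limb_correlation >= 1) {
    problems <- c(problems, "`limb_correlation` must be in [0, 1)")
  }
  if (length(problems) > 0) {
    stop("invalid synthetic configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# observer schedule implied by the 8-series assessment plan: the Doppler
# reference and the first automated application share an observer; in the
# inter-observer series (1-4) the second application goes to the other
# observer, in the intra-observer series (5-8) to the same one.
.series_observers <- function(series) {
  first <- ifelse(series %in% c(1L, 2L, 5L, 6L), "A", "B")
  second <- ifelse(series %in% 1:4,
                   ifelse(first == "A", "B", "A"),
                   first)
  list(doppler = first, set1 = first, set2 = second)
}

.truncated_limb_abi <- function(n, mu, sd, rho) {
  t_right <- numeric(n)
  t_left <- numeric(n)
  todo <- rep(TRUE, n)
  while (any(todo)) {
    k <- sum(todo)
    z1 <- stats::rnorm(k)
    z2 <- stats::rnorm(k)
    r <- mu + sd * z1
    l <- mu + sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    t_right[todo] <- r
    t_left[todo] <- l
    ok <- r > .ABI_TRUNC[1] & r < .ABI_TRUNC[2] &
      l > .ABI_TRUNC[1] & l < .ABI_TRUNC[2]
    todo[todo] <- !ok
  }
  cbind(right = t_right, left = t_left)
}

#' Generate a synthetic ABI measurement study
#'
#' Simulates the full repeated-measures design described in
#' [synthetic_config()] and returns one long-format row per recorded
#' pressure pair: subject x limb x device x observer x application set x
#' replicate. Limbs are generated (and later analysed) as separate rows;
#' both limbs of one application share its single brachial measurement.
#' Output is deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()] object.
#' @return A tibble with columns `subject_id`, `limb`, `device`, `variant`
#'   (always `"raw"`), `observer`, `series`, `set_index`, `replicate`,
#'   `brachial_mmHg`, `ankle_mmHg`, `abi`. With the default design this has
#'   56 subjects x 2 limbs x 15 pressure rows = 1680 records.
#' @examples
#' records <- generate_study(synthetic_config(seed = 7))
#' nrow(records)
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  series <- rep(1:8, config$series_sizes)
  subject_id <- sprintf("S%02d", seq_len(n))

  brachial_true <- stats::rnorm(n, config$brachial_mean, config$brachial_sd)
  abi_true <- .truncated_limb_abi(n, config$true_abi_mean, config$true_abi_sd,
                                  config$limb_correlation)

  # one random offset per (observer, device, site), fixed for the dataset
  obs_off <- array(
    stats::rnorm(2L * 3L * 2L, 0, config$observer_effect_sd),
    dim = c(2L, 3L, 2L),
    dimnames = list(c("A", "B"), .DEVICES, c("brachial", "ankle"))
  )

  drop_of <- function(device, site, set_index) {
    per_dev <- vapply(device, function(d) {
      if (d == "doppler") 0 else config$second_set_drop[[d]][[site]]
    }, numeric(1), USE.NAMES = FALSE)
    per_dev * (set_index == 2L)
  }

  sched <- .series_observers(series)

  # application grid: Doppler once, each automated device twice
  apps <- tidyr::expand_grid(
    subject_idx = seq_len(n),
    device = .DEVICES,
    set_index = 1:2
  )
  apps <- dplyr::filter(apps, !(.data$device == "doppler" & .data$set_index == 2L))
  apps$observer <- ifelse(
    apps$device == "doppler", sched$doppler[apps$subject_idx],
    ifelse(apps$set_index == 1L, sched$set1[apps$subject_idx],
           sched$set2[apps$subject_idx])
  )

  # per application x replicate: one brachial measurement shared by limbs
  reps <- tidyr::expand_grid(apps, replicate = 1:3)
  b_bias <- unname(config$device_brachial_bias[reps$device])
  b_drop <- drop_of(reps$device, "brachial", reps$set_index)
  b_off <- obs_off[cbind(reps$observer, reps$device, "brachial")]
  reps$brachial_mmHg <- brachial_true[reps$subject_idx] + b_bias + b_drop +
    b_off + stats::rnorm(nrow(reps), 0, config$replicate_noise_sd)

  # per limb: ankle measurement against the shared brachial reading
  recs <- tidyr::expand_grid(reps, limb = c("right", "left"))
  a_bias <- unname(config$device_ankle_bias[recs$device])
  a_drop <- drop_of(recs$device, "ankle", recs$set_index)
  a_off <- obs_off[cbind(recs$observer, recs$device, "ankle")]
  limb_col <- ifelse(recs$limb == "right", 1L, 2L)
  ankle_true <- abi_true[cbind(recs$subject_idx, limb_col)] *
    brachial_true[recs$subject_idx]
  recs$ankle_mmHg <- ankle_true + a_bias + a_drop + a_off +
    stats::rnorm(nrow(recs), 0, config$replicate_noise_sd)

  tibble::tibble(
    subject_id = subject_id[recs$subject_idx],
    limb = recs$limb,
    device = recs$device,
    variant = "raw",
    observer = recs$observer,
    series = series[recs$subject_idx],
    set_index = recs$set_index,
    replicate = recs$replicate,
    brachial_mmHg = recs$brachial_mmHg,
    ankle_mmHg = recs$ankle_mmHg,
    abi = recs$ankle_mmHg / recs$brachial_mmHg
  )
}

# Second-order delta-method moments of a device's triplicate-mean ABI.
# Writing D = B + b for the biased measured brachial pressure and v = 1/D,
#   ABI ~ T (1 - b v) + a v + v (eps_a + o_a - ABI (eps_b + o_b)),
# so the expansion is taken around the biased denominator mean B0 + b, and
# pressure noise propagates with weight (1 + E[ABI^2]) E[v^2].
.abi_delta_moments <- function(config, device, n_replicates) {
  Bb <- config$brachial_mean +
    config$device_brachial_bias[[device]]       # measured denominator mean
  rb2 <- (config$brachial_sd / Bb)^2
  m1 <- (1 + rb2) / Bb          # E[1/D]
  m2 <- (1 + 3 * rb2) / Bb^2    # E[1/D^2]
  var_v <- m2 - m1^2
  muT <- config$true_abi_mean
  sT2 <- config$true_abi_sd^2
  a <- config$device_ankle_bias[[device]]
  b <- config$device_brachial_bias[[device]]
  delta <- (a - muT * b) * m1                   # mean ABI shift vs truth
  slope <- 1 - b * m1                           # loading on true ABI
  bias_pressure <- a - muT * b                  # loading on shared 1/D
  var_main <- sT2 * slope^2 + bias_pressure^2 * var_v
  EABI2 <- (muT + delta)^2 + var_main
  noise <- (config$replicate_noise_sd^2 / n_replicates) * (1 + EABI2) * m2
  obs <- config$observer_effect_sd^2 * (1 + EABI2) * m2
  list(
    delta = delta, slope = slope, bias_pressure = bias_pressure,
    denominator_mean = Bb,
    var_main = var_main, var = var_main + noise + obs,
    var_v = var_v, sT2 = sT2, noise = noise, obs = obs
  )
}

#' Population CCC implied by a synthetic configuration
#'
#' Closed-form (second-order delta method) approximation to the population
#' concordance correlation coefficient between the triplicate-mean ABIs of
#' two devices under the generative model of [generate_study()], both at
#' their first application. Used as a ground-truth target in parameter
#' recovery tests; accurate to about 0.01 for default-scale configurations.
#'
#' @param config A [synthetic_config()] object.
#' @param device_a,device_b Device names (`"doppler"`, `"vicorder"`,
#'   `"vascular_explorer"`).
#' @param n_replicates Number of replicates averaged per application
#'   (default 3).
#' @return A single number in \eqn{[-1, 1]}; symmetric in the two devices.
#' @examples
#' population_ccc(synthetic_config(), "vicorder", "doppler")
#' @export
population_ccc <- function(config, device_a, device_b, n_replicates = 3) {
  stopifnot(inherits(config, "synthetic_config"))
  device_a <- match.arg(device_a, .DEVICES)
  device_b <- match.arg(device_b, .DEVICES)
  A <- .abi_delta_moments(config, device_a, n_replicates)
  B <- .abi_delta_moments(config, device_b, n_replicates)
  # the 1/D terms of the two devices are driven by the same brachial
  # pressure, hence (to first order) perfectly correlated
  cov_v <- config$brachial_sd^2 /
    (A$denominator_mean^2 * B$denominator_mean^2)
  covar <- A$sT2 * A$slope * B$slope +
    A$bias_pressure * B$bias_pressure * cov_v
  denom <- A$var + B$var + (A$delta - B$delta)^2
  if (denom == 0) return(1)
  2 * covar / denom
}

#' Population within-set OCCC implied by a synthetic configuration
#'
#' Delta-method approximation to the population OCCC of one device's
#' replicate triplet (replicates of a single application, which share the
#' device bias and the observer offset and differ only by replicate
#' noise). Observer offsets are assumed balanced across the two observers
#' of the default design, contributing half their variance between rows.
#'
#' @inheritParams population_ccc
#' @param device Device name.
#' @return A single number in \eqn{[0, 1]}.
#' @export
population_within_set_occc <- function(config, device) {
  stopifnot(inherits(config, "synthetic_config"))
  device <- match.arg(device, .DEVICES)
  M <- .abi_delta_moments(config, device, n_replicates = 1)
  between <- M$var_main + M$obs / 2
  if (M$noise == 0) return(1)
  between / (between + M$noise)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic ABI study configuration\n")
  cat("  subjects:", x$n_subjects, "in series of",
      paste(x$series_sizes, collapse = ", "), "\n")
  cat(sprintf("  true ABI ~ N(%.2f, %.2f^2) truncated to (%.1f, %.1f); limb correlation %.2f\n",
              x$true_abi_mean, x$true_abi_sd, .ABI_TRUNC[1], .ABI_TRUNC[2],
              x$limb_correlation))
  cat(sprintf("  brachial pressure ~ N(%.0f, %.0f^2) mmHg\n",
              x$brachial_mean, x$brachial_sd))
  cat(sprintf("  replicate noise sd %.1f mmHg; observer effect sd %.1f mmHg; seed %d\n",
              x$replicate_noise_sd, x$observer_effect_sd, x$seed))
  invisible(x)
}
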