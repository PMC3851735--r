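---
title: "Agreement methods for multi-device ABI studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement methods for multi-device ABI studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abiagree)
```

## The statistical problem

A method-comparison study of ankle–brachial index (ABI) devices asks
several distinct agreement questions of the same repeated-measures data:
do a device's back-to-back replicates agree with each other (within-set
agreement), does the device agree with the Doppler reference, and do two
applications of the device — by the same or by different observers —
agree with each other? Each question is a comparison of paired (or
J-tupled) continuous measurements on the same sampling units, and each
is answered here with the same core statistic: the concordance
correlation coefficient.

Throughout, a *unit* is one limb-level record: left- and right-side
measurements are treated as independent rows. This mirrors the usual
design of ABI studies, where limbs are scored and interpreted
separately; the package nevertheless exposes subject-wise jackknife
deletion (`jackknife_unit = "subject"`) as a sensitivity analysis,
since limbs of one subject are positively correlated and unit-wise
deletion can slightly understate standard errors when that correlation
is strong.

## Estimators

For paired vectors the package uses Lin's moment estimator

$$\hat\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

with all second moments on the $1/n$ convention of the original
estimator. The convention is applied consistently to variances and
covariances, so switching to $1/(n-1)$ would cancel from the ratio — a
property the test suite checks implicitly by comparing against an
independent brute-force oracle. The overall CCC for $J \ge 2$ columns,

$$\mathrm{OCCC} = \frac{2\sum_{j<k} s_{jk}}
  {\sum_{j<k}\left(s_j^2 + s_k^2 + (\bar x_j - \bar x_k)^2\right)},$$

is the pairwise-denominator-weighted mean of all pairwise CCCs, reduces
exactly to the CCC at $J = 2$, and is invariant under column
permutation.

A numerical detail worth stating: the pairwise moment sums are
accumulated with explicit per-pair arithmetic rather than a BLAS
cross-product, so that identical columns produce bitwise-identical
numerator and denominator and perfect agreement returns exactly 1. The
pipeline's noise-free invariant (every concordance exactly 1, every
bias exactly 0) relies on this.

## Jackknife inference on the Fisher scale

Confidence bounds come from leave-one-out resampling of the Fisher
transform $z = \operatorname{atanh}(\hat\rho_c)$. With $g$ deletion
units, pseudovalues $\hat z_i = g z - (g-1) z_{(-i)}$ give
$\mathrm{SE} = \mathrm{sd}(\hat z_i)/\sqrt{g}$ and the interval
$\tanh(z \pm q\,\mathrm{SE})$. Choices made where convention leaves
room:

* **Quantile.** $q$ is the standard-normal quantile, not a Student-t
  quantile; the pseudovalue construction is conventionally paired with
  the normal reference, and at the study's $n \approx 112$ the
  difference is negligible. The confidence level is configurable.
* **Clamping.** Leave-one-out samples of near-perfect data can produce
  $|\hat\rho_c| = 1$, where atanh is infinite. Values within $10^{-12}$
  of $\pm 1$ are clamped to $\pm(1 - 10^{-12})$ with a single warning
  per resampling pass. When clamping makes $\tanh$ of the upper bound
  fall a hair below a raw estimate of exactly 1, the interval is widened
  to contain the point estimate.
* **Degenerate resamples.** A leave-one-out subsample whose CCC is
  undefined (all remaining values constant and equal) aborts with an
  error naming the offending unit. Silently skipping such resamples
  would bias the SE downward, and their occurrence signals data that
  should not be jackknifed at all.

The same pseudovalue machinery tests the difference of two CCCs
computed on the same units — for instance each automated device against
the same Doppler column, where the two coefficients are strongly
correlated and independent-sample z-tests would be wrong. The
difference is taken on the Fisher scale by default
(`scale = "fisher"`), consistent with the CI construction and better
normalized for coefficients near 1; the raw-coefficient scale is
available behind `scale = "raw"`. The two give identical self-
comparisons and the same difference sign; they differ only in the SE
normalization.

## Bias and Bland–Altman analysis

Biases are arithmetic means of paired differences, tested with
two-sided one-sample t-tests ($n-1$ df, sample sd); biases of two
methods against a common reference are compared with a paired t-test of
the individual difference vectors. Bland–Altman limits of agreement use
the fixed 1.96 multiplier on the sample sd of the differences. If all
differences are identical the t-test degenerates: a zero mean returns
$t = 0, p = 1$, a nonzero mean returns $p = 0$ (bias established with
certainty under the model) — these branches are handled analytically
rather than refused.

Wilcoxon signed-rank comparisons of acceptance scores and durations
drop zero-difference pairs (Wilcoxon's original policy), use the exact
distribution below 20 informative pairs where ties permit, and the
normal approximation with continuity correction otherwise. Following
the exploratory character of such feasibility studies, no
multiple-testing correction is applied anywhere; the analysis report
labels its p-values "suggestive" in its metadata.

## The synthetic study generator

`generate_study()` emulates the statistical structure the pipeline
assumes, with known ground truth:

* **Design.** 56 subjects in 8 series of 7; per subject one Doppler
  application (one replicate triplet) and two applications of each
  automated device (a triplet each); series 1–4 assign the two
  applications to different observers, series 5–8 to the same one.
  This yields 15 pressure rows per limb, 1680 records in all.
* **Truth.** Subject-level brachial pressure $B \sim N(130, 15^2)$
  mmHg; per-limb true ABI $T$ bivariate normal across limbs with
  correlation 0.6, mean 1.10, sd 0.10, truncated to (0.3, 1.6). The
  limb correlation is a free parameter of the model — 0.6 is a
  mid-range choice for bilateral vascular indices, exposed in the
  configuration rather than asserted.
* **Measurement model.** Noise and biases are additive on the
  *pressure* scale, because that is where device differences
  physically arise (a deflation-timing device reads brachial pressure
  low; an inflation-based device reads ankle pressure high). Each
  recorded pressure adds a device-and-site bias, a fixed
  second-application drop (defaults −5.2/−7.5 mmHg brachial/ankle for
  the deflation device, −4.6/−4.4 for the inflation device), a random
  offset per (observer, device, site) drawn once per dataset
  (sd 2 mmHg), and independent replicate noise (sd 4 mmHg). ABI is
  always the measured-ankle / measured-brachial ratio, with both limbs
  sharing one brachial measurement per application, as when only the
  right arm is cuffed.
* **Calibration.** The default device biases are not round numbers:
  they are solved numerically so that the model-implied mean ABI
  inflation relative to Doppler is exactly +0.05 (deflation device,
  via a negative brachial bias) and +0.13 (inflation device, positive
  ankle bias). A first-order delta calibration would be off by a few
  thousandths because the brachial bias also shifts the ABI
  denominator; the package inverts the full expectation by quadrature
  instead. The replicate-noise and observer-effect sds are not
  identified by any published quantity; the defaults produce
  within-set concordances in the realistic 0.7–0.85 range and are
  tuning knobs for test power, not estimates of any real study.

`population_ccc()` and `population_within_set_occc()` provide
closed-form (second-order delta method) ground-truth targets for
recovery tests, accurate to about 0.01 against Monte-Carlo estimates at
the default parameter scale — the expansion is taken around the
*biased* denominator mean $B_0 + b$ and propagates pressure noise with
weight $(1 + E[\mathrm{ABI}^2])\,E[1/D^2]$, both of which matter at
this accuracy.

What the generator deliberately does **not** emulate: PPG waveform
morphology and trace-correction mechanics (revised variants are just
additional input columns analysed identically), diseased low-ABI
vessels (reachable via configuration but not mechanistically modelled),
heteroscedastic or non-Gaussian measurement error, and drift within a
replicate triplet. Passing recovery tests therefore demonstrate that
the estimators do what they claim under a linear-Gaussian pressure
model — not that any real device behaves this way.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route:
explicit brute-force oracles (1e-12 agreement for CCC, OCCC and
jackknife SEs on 100 random matrices), closed-form population values
(CCC recovery within 3 SEM over 1000 replicates at $n = 500$),
frequentist operating characteristics (jackknife CI coverage within
[0.92, 0.98] at nominal 95%, $n = 200$, 1000 replicates; difference-
test type-I error within [0.03, 0.07] at $\alpha = 0.05$, 1000
replicates), exactness on noise-free data, and parameter recovery of
the configured ABI inflations at the study's own size (200 replicate
studies). These sizes keep the full suite around one to two minutes on
a single core while leaving Monte-Carlo error well below the tested
tolerances.

## Known limitations

* Jackknife variance of a correlation-type statistic is first-order;
  for $n \lesssim 30$ units the intervals can undercover. The study
  design's 112 limb-records are comfortable; small subgroup analyses
  are not.
* The OCCC treats all column pairs exchangeably; it is not a
  longitudinal or weighted CCC and should not be used where replicate
  order carries meaning beyond a shared application.
* The difference test assumes both statistics are computed on exactly
  the same rows; the pipeline enforces complete-case pairing per
  analysis (a limb missing one device is dropped from that comparison
  only).
* Closed-form population targets are delta-method approximations;
  configurations with brachial coefficient of variation far above the
  default ~12% will exceed their stated 0.01 accuracy.
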