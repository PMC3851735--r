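Package: abiagree
Title: Agreement Analysis for Multi-Device Ankle-Brachial Index Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for method-comparison studies of ankle-brachial index
    (ABI) measurement devices. Implements Lin's concordance correlation
    coefficient (CCC) and its multi-rater generalization (the overall CCC,
    OCCC), jackknife standard errors and confidence intervals on the Fisher
    z scale, a same-sample jackknife test for the difference of two CCCs,
    bias estimation with one-sample and paired t-tests, and Bland-Altman
    limits of agreement. A synthetic-data generator emulates a multi-device,
    multi-observer repeated-measures ABI study design (replicate triplets,
    device-specific pressure biases, observer effects, between-application
    pressure drops) so every analysis stage can be exercised against known
    ground truth. A pipeline layer orchestrates within-set triplicate
    agreement, agreement with Doppler sonography, inter- and intra-observer
    concordance, and feasibility summaries on long-format measurement data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
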