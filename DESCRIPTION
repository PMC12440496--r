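Package: mrmediation
Title: Two-Sample Mendelian Randomization with Metabolite Mediation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) and two-step
    MR mediation analysis from GWAS summary statistics. Reads and harmonizes
    exposure/outcome summary-statistic tables onto a shared effect-allele
    frame (including palindromic-variant frequency alignment), selects
    instrumental variants by p-value threshold, greedy LD clumping,
    F-statistic and Steiger directionality filters, and estimates causal
    effects with inverse-variance weighted (fixed or REML random effects),
    MR-Egger, weighted-median and MR-PRESSO estimators with leave-one-out
    diagnostics. A two-stage mediation layer combines exposure-mediator,
    mediator-outcome and exposure-outcome fits into indirect and direct
    effects with Sobel tests, delta-method confidence intervals and
    proportions mediated. A seeded synthetic summary-statistic generator
    with known causal and mediation structure supports calibration and
    recovery studies without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
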