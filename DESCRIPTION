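Package: mrmediate
Title: Two-Sample Mendelian Randomization with Mediation and Sensitivity Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: reading and harmonizing summary-statistic tables,
    instrument selection by p-value threshold and LD clumping with
    instrument-strength (F statistic) screening and power analysis, causal
    estimation by inverse-variance weighting, MR-Egger regression, weighted
    median and mode-based estimators, a Bayesian-weighted MR estimator that
    down-weights outlying instruments, a sensitivity battery (Cochran Q,
    Egger intercept, MR-PRESSO, leave-one-out), and two-step MR mediation
    analysis with delta-method confidence intervals. Includes a synthetic
    summary-statistic generator for exposure-mediator-outcome triplets and
    many-exposure screening panels with known ground truth, and a pipeline
    orchestrating forward screening, validation, reverse MR, and mediation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
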