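Package: mrmediate
Title: Stepwise Two-Sample Mendelian Randomization Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for stepwise two-sample Mendelian randomization (MR)
    mediation analysis from GWAS summary statistics: instrument selection
    (genome-wide significance, greedy LD clumping, F-statistic filtering),
    exposure/outcome allele harmonization with palindromic-SNP handling, six
    causal-effect estimators (fixed and multiplicative-random-effects
    inverse-variance weighted, MR-Egger, weighted median, simple and weighted
    mode, Bayesian-weighted MR), heterogeneity and pleiotropy diagnostics
    (Cochran's Q, Egger intercept, leave-one-out, funnel tables), multiple
    testing correction, multi-exposure screening, reverse MR, and
    product-of-coefficients mediation decomposition with delta-method
    confidence intervals. Includes a synthetic GWAS summary-statistics
    simulator with a known exposure-mediator-outcome causal chain for
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
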