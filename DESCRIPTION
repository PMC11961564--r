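Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    screens and two-step mediation analysis from GWAS summary statistics.
    Implements instrument selection (p-value thresholding with fallback,
    greedy LD clumping, F-statistic filtering), allele harmonization with
    palindromic-variant removal, the inverse-variance-weighted, MR-Egger,
    weighted-median and weighted-mode estimators, sensitivity diagnostics
    (Cochran's Q, Egger intercept, MR-PRESSO, leave-one-out), Bonferroni
    screening with replication, and product-of-coefficients mediation with
    delta-method uncertainty. Ships a summary-level GWAS simulator with
    known causal, pleiotropic and mediation ground truth so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
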