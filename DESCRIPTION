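Package: twostepmr
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: instrument selection (p-value thresholding, greedy
    LD clumping, F-statistic screening, confounder-trait exclusion), allele
    harmonization across exposure and outcome datasets, the standard
    estimator family (inverse-variance weighted, MR-Egger, weighted median,
    weighted and simple mode), heterogeneity and pleiotropy diagnostics
    (Cochran's Q, Egger intercept, leave-one-out), fixed- and random-effects
    meta-analysis of log odds ratios for replication, and two-step mediation
    MR with a delta-method proportion mediated. Includes a summary-level
    GWAS simulator with a known exposure-mediator-outcome causal structure
    for calibration and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
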