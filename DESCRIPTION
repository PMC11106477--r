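Package: bloodcellmr
Title: Mendelian Randomization of Blood-Cell Traits on Inflammatory Bowel Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization of
    complete-blood-count traits on Crohn's disease and ulcerative colitis:
    instrument selection with LD clumping, proxy lookup and confounder
    screening; harmonization of exposure and outcome summary statistics; six
    univariable causal estimators (fixed and multiplicative-random-effects
    IVW, simple, weighted and penalized weighted median, MR-Egger) with
    Cochran's Q and Egger-intercept diagnostics; multivariable MR via
    Bayesian model averaging with iterative Q and Cook's-distance outlier
    pruning; and restricted-cubic-spline logistic dose-response analysis of
    an individual-level case-control cohort. A synthetic-data module
    generates GWAS summary statistics, LD matrices, confounder catalogs and
    blood-count cohorts with known ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
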