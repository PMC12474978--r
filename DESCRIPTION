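Package: vepbench
Title: Real-World Cohort Benchmarks for Variant Effect Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Benchmarks pathogenicity calls from computational variant effect
    predictors (VEPs) against the statistical structure of real-world cancer
    cohorts. Implements four validation benchmarks: rediscovery of known
    driver mutations by ROC analysis with DeLong confidence intervals and
    tests, enrichment of reclassified-pathogenic variants at protein binding
    residues, inverse-probability-of-treatment-weighted left-truncated
    survival analysis with a relative-risk performance metric, and pathway
    mutual exclusivity testing with TMB-adjusted logistic regression.
    Includes score calibration (Youden-type cutpoints, built-in class maps,
    q-value rules), a trinucleotide-context (SBS96) neutral-variant
    simulator, a random-forest score ensemble with gene-holdout
    cross-validation, and a synthetic cohort generator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
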