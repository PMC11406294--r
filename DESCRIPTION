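Package: cfrnadx
Title: Plasma Cell-Free RNA Diagnostics for Pediatric Inflammatory Syndromes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for differential diagnosis of pediatric
    inflammatory syndromes (Kawasaki disease, MIS-C, viral and bacterial
    infection) from plasma cell-free RNA count matrices: sample quality
    filtering, median-of-ratios normalization with a negative-binomial
    variance-stabilizing transform and strict train-to-test projection,
    per-gene negative-binomial Wald tests with BH correction and gene-level
    ROC-AUC, filter-cascade gene-panel selection, regularized-logistic binary
    classification with Youden thresholds and a model bake-off harness,
    one-vs-one score-stacked multiclass classification, non-negative
    least-squares cell-type-of-origin deconvolution, and per-patient
    diagnostic reports with organ-injury z-scores. Includes a seeded
    synthetic cohort generator with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    e1071,
    class,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
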