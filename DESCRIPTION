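Package: vitalnet
Title: Multi-Omics Recurrent Neural Classification of Patient Vital Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying cancer patients as dead
    or alive from multi-omics profiles (copy number, gene expression, DNA
    methylation, miRNA abundance and protein levels). Provides a seeded
    synthetic cohort generator emulating GDC-style feature-by-sample
    matrices, three-stage missing-value preprocessing (zero-prevalence
    feature filter, missing-sample filter, k-nearest-neighbour imputation,
    null-feature removal), a multi-branch LSTM classifier with an
    input-subset switching layer, weight-sensitivity restart training and
    hidden-unit adaptation, survival-oriented evaluation (confusion-matrix
    metrics, Harrell concordance index, Brier score, ROC, two-group
    log-rank test), and ratio-based marker discovery with rule-based drug
    target triage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
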