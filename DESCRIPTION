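Package: readervar
Title: Observer Variability and Diagnostic Accuracy in Multi-Reader Imaging Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-reader diagnostic imaging studies with
    ordinal confidence annotations, motivated by slice-level adhesion detection
    on abdominal cine-MRI. Converts bounding-box annotations with 5-point
    confidence scores into slice-by-observer score tables, binarizes them at
    per-reader clinical-significance thresholds, and quantifies inter-observer
    agreement (Fleiss' kappa, unanimity percentage agreement), intra-observer
    agreement (Cohen's kappa) and diagnostic accuracy (per-reader ROC curves,
    trapezoidal AUC, diagonally averaged group ROC curves). Inference uses
    case-resampling bootstrap confidence intervals, observer-permutation tests
    for group differences, and a two-way (reader-by-case) bootstrap z-test for
    group AUC differences. Includes a seeded latent-signal simulator of
    multi-reader studies with experience-linked reader discrimination for
    validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
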