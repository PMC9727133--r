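Package: msynscreen
Title: Anthropometric Screening Indices for Metabolic Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes seven anthropometric adiposity indices (BMI, waist
    circumference, waist-to-height ratio, A Body Shape Index, Body Roundness
    Index, conicity index, Visceral Adiposity Index) from raw anthropometry and
    fasting biochemistry, classifies metabolic syndrome by the NCEP ATP III
    rule, and evaluates each index as a screening marker via ROC curves, AUC
    confidence intervals and Youden-optimal cutoffs, stratified by sex.
    Includes a synthetic cohort generator with known-truth binormal modes for
    validating the ROC machinery, and a reproducible end-to-end reporting
    pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
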