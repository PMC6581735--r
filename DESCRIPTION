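Package: sdconnect
Title: Connectome-Based Biomarkers for Subclinical Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted functional brain networks from ROI time series,
    screens edge weights with leakage-avoiding two-sample tests, trains
    RBF-SVM classifiers on anatomical-region, sliding-window and
    random-selection connection sets under leave-one-out cross-validation,
    and profiles dysfunctional regions and subregions by connection counts
    and weighted node degree. Includes a synthetic-cohort generator with
    planted group-differential connectivity so the whole pipeline is
    testable without access to fMRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
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
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
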