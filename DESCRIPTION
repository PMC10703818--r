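Package: felgrim
Title: Automated Feline Grimace Scale Scoring from Facial Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated acute-pain assessment in cats with the
    Feline Grimace Scale (FGS). Implements the 37-landmark facial schema
    with its five action units, annotation file input/output and
    validation, face alignment and edge-filter preprocessing, the
    augmentation recipe used for landmark-detector training, 35
    similarity-invariant geometric descriptors (angles, distance ratios,
    area ratios), FGS total-score computation with multi-rater
    aggregation rules, gradient-boosted prediction models (binary,
    regression and ordinal tasks) with cross-validated grid search,
    recursive feature elimination and Boruta-Shapley feature selection,
    NRMSE evaluation of landmark predictors, a small reference
    convolutional landmark network, and a synthetic cat-face generator
    so the full pipeline is testable without clinical image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    generics,
    rlang,
    ggplot2,
    stats,
    utils,
    jsonlite,
    yaml,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
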