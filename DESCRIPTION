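Package: painvol
Title: Pain Volatility Classes from Diary Apps: Consensus Feature
    Selection and Ensemble Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for defining and predicting pain volatility from
    longitudinal pain-diary records. Pain volatility is the mean absolute
    change between consecutive pain severity ratings within a 30-day
    observation window. The package derives low/high volatility classes by
    one-dimensional k-means thresholding, extracts a 132-feature
    representation of each user's first month of records, builds balanced
    training sets by stratified cross-validation plus repeated random
    under-sampling, selects features by consensus across Gini impurity,
    information gain and Boruta rankings, trains random-forest and
    penalized logistic-regression classifiers, and consolidates
    per-subsample predictions by majority voting. A seeded synthetic-cohort
    generator emulates app-recorded pain diaries with planted volatility
    classes for validation and experimentation.
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
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
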