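Package: bdefs
Title: Binary Differential-Evolution Feature Selection for Deep Image Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A wrapper feature-selection toolkit for high-dimensional deep
    features from histopathological and other biological images. Extracts
    fixed-length representations with a frozen convolutional backbone, global
    average pooling and a trainable two-layer head; selects compact feature
    subsets with a binary differential-evolution search driven by a
    sparsity-penalised classification-error fitness; and benchmarks the
    selected subsets across neural-network, support-vector-machine and
    tree-ensemble classifiers with a full multiclass metric report (macro
    precision/recall/F1, one-vs-rest AUC, balanced accuracy, Cohen's kappa).
    Includes synthetic fixtures with planted informative features, an
    exhaustive-search oracle for small dimensions, and selection-frequency
    analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
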