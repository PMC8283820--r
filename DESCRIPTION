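Package: missboost
Title: Iterative Gradient-Boosted-Tree Imputation for Mixed-Type Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputation of missing values in mixed continuous/categorical
    tables by an iterative column-wise gradient-boosted-tree algorithm, with
    mean/median, k-nearest-neighbour, soft-thresholded-SVD and
    chained-equations baselines. Includes a missing-completely-at-random
    masking harness for RMSE/PFC benchmarking of imputers, missingness
    exploration backends (column summaries, missingness-pattern dendrograms,
    PCA and t-SNE embeddings with k-means and elbow-based cluster-number
    suggestion), penalized and tree-based feature ranking, and
    response-excluded cross-validated prediction with ROC/PR metrics.
    Deterministic synthetic fixture generators with known ground truth
    support benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    glmnet,
    xgboost,
    ranger,
    class,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
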