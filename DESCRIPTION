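Package: aiwrap
Title: Surrogate-Assisted Wrapper Feature Selection for High-Dimensional Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements AIWrap, a surrogate-assisted wrapper feature-selection
    algorithm for continuous outcomes in high-dimensional tabular data. A
    random-forest performance prediction model (PPM), trained on feature-subset /
    cross-validated-RMSE pairs, stands in for most model-building calls inside a
    genetic-algorithm wrapper search; candidates whose predicted performance
    reaches the best quartile of known performances are validated with real
    penalized fits. The coarse feature set is then refined by embedded LASSO
    selection over all two-way interaction terms, and optionally by a
    bootstrap out-of-bag importance filter with a genetic-algorithm threshold
    search. The package also provides the Standard Wrapper (StW) baseline in
    which every candidate is evaluated by a real fit, a simulation-study
    harness (correlated multivariate-normal features, marginal and pairwise
    interaction outcome models), and evaluation metrics (selection F1, test
    RMSE, selection-frequency AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    randomForest,
    MASS,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
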