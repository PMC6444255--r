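Package: longsign
Title: Sign-Average Pseudogenes and Sparse Logistic Feature Selection for
    Longitudinal Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature selection for longitudinal two-group gene expression
    studies. Each gene's time course is collapsed to one value per subject by
    the sign average: expression at each time point is multiplied by the sign
    of that time point's estimated group effect before averaging, so opposite
    time effects do not cancel. Sparse logistic classifiers are then fit on the
    resulting pseudogene matrix by coordinate-descent LASSO or threshold
    gradient descent regularization (TGDR), tuned by stratified k-fold
    cross-validation. Includes mean/median/first-principal-component summary
    comparators, a separate-per-time-point strategy, predictive and stability
    metrics (error rate, belief confusion metric, area under the
    precision-recall curve, pairwise-Jaccard Rand index, gene-list overlap
    test), and a self-contained simulation framework with alternating- and
    monotonic-effect designs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    limma,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
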