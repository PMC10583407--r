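Package: sparsellgmn
Title: Sparse Log-Linearized Gaussian Mixture Networks for Clinical Index Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification and simultaneous automatic index selection on
    small clinical feature tables with a log-linearized Gaussian mixture
    network (LLGMN) preceded by an L1-regularized elementwise
    dimensionality-reduction layer, trained end-to-end by proximal
    stochastic gradient descent so that uninformative index weights become
    exactly zero.  Includes stratified cross-validation orchestration,
    permutation importance, comparison methods (stepwise partial
    Kullback-Leibler information elimination and Lasso regression with
    coordinate descent), ROC analysis with DeLong tests and Holm
    adjustment, Fisher/Yule association measures, the Brunner-Munzel test,
    a tree-structured Parzen estimator for the regularization coefficient,
    and synthetic cohort and sparse-signal data generators for end-to-end
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
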