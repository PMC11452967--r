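Package: mtgwp
Title: Multi-Trait Genome-Wide Prediction with Sparse Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-trait genome-wide prediction from SNP marker matrices with
    sparsity-constrained neural networks. Implements a multi-task LassoNet
    (residual network with an L1-penalized linear skip connection, a hierarchy
    constraint tying each feature's hidden-layer weights to its skip
    coefficient, an exact hierarchical proximal operator, and a dense-to-sparse
    regularization path with per-trait marker selection export), a gated
    adaptive network built from stacked gated feature learning units with
    learnable sparse feature masks, gradient-boosting and multilayer-perceptron
    baselines, evaluation metrics for multi-trait regression and multi-class
    classification with seed ensembling, Bayesian (tree-structured Parzen
    estimator) hyperparameter search scored by k-fold cross-validation, and a
    synthetic genotype-phenotype simulator with blockwise linkage
    disequilibrium, pleiotropic QTL architectures and target heritability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    pROC,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
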