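#' Gradient-boosted decision tree baseline
#'
#' Fits the standard GBDT comparator on the training partition (one boosted
#' regressor per trait, or a single multi-class softprob booster) and
#' predicts the test partition. Uses the xgboost library; single-threaded
#' and seeded for reproducibility.
#'
#' @param X `n x p` marker matrix (or [genotype_matrix()]).
#' @param Y traits (matrix, labels, or [trait_data()]).
#' @param split a [split_data()] result.
#' @param params named list overriding the defaults
#'   `nrounds = 200, eta = 0.05, max_depth = 4, subsample = 0.8,
#'   colsample_bytree = 0.8, early_stopping = 20` (early stopping monitors
#'   the validation partition).
#' @param seed integer seed.
#' @param task `"regression"` or `"classification"`.
#' @return list with `predictions` (test-set trait matrix, or class
#'   probability matrix) and `models` (fitted boosters).
#' @export
fit_gbdt_baseline <- function(X, Y, split, params = list(), seed = 1L,
                              task = c("regression", "classification")) {
  task <- match.arg(task)
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop_mtgwp("the xgboost package is required for the GBDT baseline; ",
               "install it or drop 'gbdt' from the model list",
               class = "mtgwp_missing_dependency")
  }
  xy <- as_xy(X, Y, task)
  pr <- modifyList(list(nrounds = 200, eta = 0.05, max_depth = 4,
                        subsample = 0.8, colsample_bytree = 0.8,
                        early_stopping = 20), params)
  Xtr <- xy$X[split$train_idx, , drop = FALSE]
  Xva <- xy$X[split$val_idx, , drop = FALSE]
  Xte <- xy$X[split$test_idx, , drop = FALSE]
  with_seed(seed, {
    common <- list(eta = pr$eta, max_depth = pr$max_depth,
                   subsample = pr$subsample,
                   colsample_bytree = pr$colsample_bytree, nthread = 1)
    if (task == "regression") {
      k <- ncol(xy$Y)
      models <- vector("list", k)
      preds <- matrix(0, length(split$test_idx), k)
      for (t in seq_len(k)) {
        dtr <- xgboost::xgb.DMatrix(Xtr, label = xy$Y[split$train_idx, t])
        dva <- xgboost::xgb.DMatrix(Xva, label = xy$Y[split$val_idx, t])
        models[[t]] <- xgboost::xgb.train(
          params = c(common, objective = "reg:squarederror"),
          data = dtr, nrounds = pr$nrounds, evals = list(val = dva),
          early_stopping_rounds = pr$early_stopping, verbose = 0)
        preds[, t] <- predict(models[[t]], Xte)
      }
      colnames(preds) <- colnames(xy$Y)
      list(predictions = preds, models = models)
    } else {
      K <- xy$k
      dtr <- xgboost::xgb.DMatrix(Xtr, label = xy$Y[split$train_idx])
      dva <- xgboost::xgb.DMatrix(Xva, label = xy$Y[split$val_idx])
      model <- xgboost::xgb.train(
        params = c(common, objective = "multi:softprob", num_class = K),
        data = dtr, nrounds = pr$nrounds, evals = list(val = dva),
        early_stopping_rounds = pr$early_stopping, verbose = 0)
      probs <- predict(model, Xte)
      if (!is.matrix(probs)) probs <- matrix(probs, ncol = K, byrow = TRUE)
      list(predictions = unname(probs), models = list(model))
    }
  })
}

#' Plain multi-task MLP baseline
#'
#' The unregularized feed-forward network: shared hidden layers and a joint
#' k-output head, trained with early stopping. Implemented as the LassoNet
#' dense phase with `lambda = 0` and `nu = Inf` (no hierarchy constraint),
#' which is exactly the architecture's unconstrained limit.
#'
#' @inheritParams fit_gbdt_baseline
#' @param params named list overriding [lassonet_config()] fields (e.g.
#'   `hidden_sizes`, `learning_rate`, `epochs_dense`).
#' @return list with `predictions` (test-set predictions; class probabilities
#'   for classification) and `model` (the fitted `lassonet_model`).
#' @export
fit_mlp_baseline <- function(X, Y, split, params = list(), seed = 1L,
                             task = c("regression", "classification")) {
  task <- match.arg(task)
  cfg_args <- modifyList(list(task = task, seed = seed, nu = Inf),
                         params)
  config <- do.call(lassonet_config, cfg_args)
  model <- train_dense(X, Y, split, config)
  if (inherits(X, "genotype_matrix")) X <- X$values
  Xte <- as.matrix(X)[split$test_idx, , drop = FALSE]
  preds <- if (task == "classification") {
    predict(model, Xte, type = "probs")
  } else {
    predict(model, Xte)
  }
  list(predictions = preds, model = model)
}
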