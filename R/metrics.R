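#' Mean squared error over all traits
#'
#' Mean of the `n * k` squared residuals between observed and predicted
#' trait matrices.
#'
#' @param Y,Yhat `n x k` numeric matrices (or vectors for k = 1).
#' @return a single number.
#' @export
mse_mean <- function(Y, Yhat) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) {
    stop_mtgwp("Y and Yhat must have identical dimensions",
               class = "mtgwp_precondition_error")
  }
  mean((Y - Yhat)^2)
}

#' Pearson correlation averaged across traits
#'
#' Per-trait Pearson correlation between observed and predicted values,
#' arithmetically averaged over the k traits.
#'
#' @param Y,Yhat `n x k` numeric matrices (or vectors for k = 1).
#' @return a single number in \[-1, 1\].
#' @export
pearson_r_mean <- function(Y, Yhat) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) {
    stop_mtgwp("Y and Yhat must have identical dimensions",
               class = "mtgwp_precondition_error")
  }
  rs <- vapply(seq_len(ncol(Y)), function(t) {
    if (sd(Y[, t]) == 0 || sd(Yhat[, t]) == 0) {
      stop_mtgwp("correlation undefined for constant trait column ", t,
                 class = "mtgwp_precondition_error")
    }
    cor(Y[, t], Yhat[, t])
  }, numeric(1))
  mean(rs)
}

#' Classification accuracy (percentage)
#'
#' @param labels,predicted_labels integer class labels of equal length.
#' @return percentage of correct predictions on the 0-100 scale.
#' @export
accuracy <- function(labels, predicted_labels) {
  if (length(labels) == 0L || length(labels) != length(predicted_labels)) {
    stop_mtgwp("labels and predictions must be non-empty and equal-length",
               class = "mtgwp_precondition_error")
  }
  100 * mean(as.integer(labels) == as.integer(predicted_labels))
}

#' Macro-averaged one-vs-rest AUC (percentage)
#'
#' For each class present in the labels, the area under the ROC curve of
#' that class's predicted probability against the one-vs-rest indicator;
#' classes absent from the labels are excluded with a warning. The per-class
#' AUCs are macro-averaged and reported on the 0-100 scale.
#'
#' @param labels integer labels in `0..K-1`.
#' @param class_probabilities `n x K` matrix of predicted class
#'   probabilities, rows summing to 1.
#' @return macro AUC percentage in \[0, 100\].
#' @export
auc_macro <- function(labels, class_probabilities) {
  P <- as.matrix(class_probabilities)
  labels <- as.integer(labels)
  if (nrow(P) != length(labels)) {
    stop_mtgwp("probability rows must match labels",
               class = "mtgwp_precondition_error")
  }
  if (any(abs(rowSums(P) - 1) > 1e-6)) {
    stop_mtgwp("probability rows must sum to 1",
               class = "mtgwp_precondition_error")
  }
  K <- ncol(P)
  present <- sort(unique(labels))
  absent <- setdiff(seq_len(K) - 1L, present)
  if (length(absent) > 0L) {
    warning("classes absent from labels excluded from macro AUC: ",
            paste(absent, collapse = ", "))
  }
  if (length(present) < 2L) {
    stop_mtgwp("macro AUC needs at least two classes present",
               class = "mtgwp_precondition_error")
  }
  aucs <- vapply(present, function(cl) {
    resp <- as.integer(labels == cl)
    roc <- pROC::roc(response = resp, predictor = P[, cl + 1L],
                     levels = c(0, 1), direction = "<", quiet = TRUE)
    as.numeric(pROC::auc(roc))
  }, numeric(1))
  100 * mean(aucs)
}

#' Multi-class Brier score
#'
#' Mean over samples of the squared Euclidean distance between the predicted
#' class-probability vector and the one-hot outcome,
#' `mean_i sum_k (p_ik - o_ik)^2` — the original multi-class definition with
#' range \[0, 2\] (a uniform prediction over K classes scores `(K-1)/K`).
#' Set `normalize = TRUE` for the variant divided by 2 with range \[0, 1\].
#'
#' @param labels integer labels in `0..K-1`.
#' @param class_probabilities `n x K` probability matrix, rows summing to 1.
#' @param normalize divide by 2 (default `FALSE`, the original definition).
#' @return a single number.
#' @export
brier_multiclass <- function(labels, class_probabilities, normalize = FALSE) {
  P <- as.matrix(class_probabilities)
  labels <- as.integer(labels)
  if (nrow(P) != length(labels)) {
    stop_mtgwp("probability rows must match labels",
               class = "mtgwp_precondition_error")
  }
  if (any(abs(rowSums(P) - 1) > 1e-6)) {
    stop_mtgwp("probability rows must sum to 1 (tolerance 1e-6)",
               class = "mtgwp_precondition_error")
  }
  O <- matrix(0, nrow(P), ncol(P))
  O[cbind(seq_len(nrow(P)), labels + 1L)] <- 1
  b <- mean(rowSums((P - O)^2))
  if (normalize) b / 2 else b
}

#' Evaluate a model over an ensemble of seeds
#'
#' Runs `run_fn` once per seed; each run returns test-set predictions
#' (`n x k` trait predictions for regression, `n x K` class probabilities
#' for classification). Metrics are computed per run and reported as mean
#' and standard deviation across seeds; in addition the per-run predictions
#' are averaged into an ensemble prediction whose metrics are reported
#' separately (the headline values).
#'
#' @param run_fn function of one argument (a seed) returning a prediction
#'   matrix for the test samples.
#' @param Y_test observed test traits (matrix) or labels (vector).
#' @param task `"regression"` or `"classification"`.
#' @param seeds integer vector of seeds (default `1:10`, the 10-seed
#'   ensembling protocol).
#' @return an object of class `metrics_report`: `per_seed` (data.frame of
#'   per-run metrics), `mean`, `stddev`, `ensemble` (named metric lists) and
#'   `n_seeds`.
#' @export
ensemble_evaluate <- function(run_fn, Y_test, task = c("regression", "classification"),
                              seeds = 1:10) {
  task <- match.arg(task)
  if (length(seeds) < 1L) {
    stop_mtgwp("need at least one seed", class = "mtgwp_precondition_error")
  }
  preds <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    preds[[i]] <- tryCatch(run_fn(seeds[i]), error = function(e) {
      stop_mtgwp("run failed for seed ", seeds[i], ": ", conditionMessage(e),
                 class = "mtgwp_run_error")
    })
  }
  metric_fn <- function(P) {
    if (task == "regression") {
      list(mse = mse_mean(Y_test, P), r = pearson_r_mean(Y_test, P))
    } else {
      P <- P / rowSums(P)  # mean of simplex rows stays on the simplex
      pred_lab <- max.col(P, ties.method = "first") - 1L
      list(accuracy = accuracy(Y_test, pred_lab),
           auc = auc_macro(Y_test, P),
           brier = brier_multiclass(Y_test, P))
    }
  }
  per_seed <- do.call(rbind, lapply(preds, function(P) {
    as.data.frame(metric_fn(as.matrix(P)))
  }))
  per_seed <- cbind(seed = seeds, per_seed)
  ens_pred <- Reduce(`+`, lapply(preds, as.matrix)) / length(preds)
  mnames <- setdiff(names(per_seed), "seed")
  structure(
    list(per_seed = per_seed,
         mean = as.list(colMeans(per_seed[mnames])),
         stddev = as.list(vapply(per_seed[mnames], function(x) {
           if (length(x) > 1L) sd(x) else 0
         }, numeric(1))),
         ensemble = metric_fn(ens_pred),
         ensemble_prediction = ens_pred,
         n_seeds = length(seeds)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d seeds\n", x$n_seeds))
  for (m in names(x$mean)) {
    cat(sprintf("  %s: %.4g +/- %.4g (ensemble %.4g)\n",
                m, x$mean[[m]], x$stddev[[m]], x$ensemble[[m]]))
  }
  invisible(x)
}
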