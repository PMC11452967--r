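#' Hyperparameter search-space constructors
#'
#' A search space is an ordered collection of named parameters, each
#' continuous (linear or log scale), integer, or categorical.
#'
#' @param ... parameter definitions from [param_continuous()],
#'   [param_integer()] or [param_categorical()].
#' @return an object of class `search_space`.
#' @export
search_space <- function(...) {
  params <- list(...)
  if (length(params) == 0L) {
    stop_mtgwp("search space needs at least one parameter",
               class = "mtgwp_config_error")
  }
  nm <- vapply(params, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop_mtgwp("duplicate parameter names", class = "mtgwp_config_error")
  }
  names(params) <- nm
  structure(params, class = "search_space")
}

#' @rdname search_space
#' @param name parameter name.
#' @param lower,upper ordered numeric bounds.
#' @param log sample on the log scale (continuous only).
#' @export
param_continuous <- function(name, lower, upper, log = FALSE) {
  if (!(lower < upper)) stop_mtgwp("bounds must be ordered",
                                   class = "mtgwp_config_error")
  if (log && lower <= 0) stop_mtgwp("log-scale bounds must be positive",
                                    class = "mtgwp_config_error")
  list(name = name, kind = "continuous", lower = lower, upper = upper,
       log = log)
}

#' @rdname search_space
#' @export
param_integer <- function(name, lower, upper) {
  if (!(lower < upper)) stop_mtgwp("bounds must be ordered",
                                   class = "mtgwp_config_error")
  list(name = name, kind = "integer", lower = as.integer(lower),
       upper = as.integer(upper), log = FALSE)
}

#' @rdname search_space
#' @param choices non-empty vector of categorical choices.
#' @export
param_categorical <- function(name, choices) {
  if (length(choices) == 0L) stop_mtgwp("choices must be non-empty",
                                        class = "mtgwp_config_error")
  list(name = name, kind = "categorical", choices = choices)
}

sample_param <- function(def) {
  switch(def$kind,
    continuous = if (def$log) {
      exp(runif(1, log(def$lower), log(def$upper)))
    } else {
      runif(1, def$lower, def$upper)
    },
    integer = sample(seq(def$lower, def$upper), 1L),
    categorical = def$choices[[sample.int(length(def$choices), 1L)]]
  )
}

# Parzen-estimator machinery for one parameter: density of a value under a
# set of observed values, and sampling from the mixture.
parzen_numeric <- function(obs, lower, upper) {
  n <- length(obs)
  bw <- if (n > 1L && sd(obs) > 0) 1.06 * sd(obs) * n^(-1 / 5) else 0
  bw <- max(bw, (upper - lower) / 20)
  list(obs = obs, bw = bw, lower = lower, upper = upper)
}

parzen_density <- function(pz, x) {
  prior <- 1 / (pz$upper - pz$lower)
  if (length(pz$obs) == 0L) return(prior)
  kern <- vapply(x, function(xx) {
    mean(stats::dnorm(xx, mean = pz$obs, sd = pz$bw))
  }, numeric(1))
  0.9 * kern + 0.1 * prior
}

parzen_sample <- function(pz) {
  if (length(pz$obs) == 0L) return(runif(1, pz$lower, pz$upper))
  ctr <- pz$obs[[sample.int(length(pz$obs), 1L)]]
  min(pz$upper, max(pz$lower, stats::rnorm(1, ctr, pz$bw)))
}

tpe_suggest <- function(space, trials, n_candidates = 24L, gamma = 0.25) {
  ok <- trials[!trials$failed, , drop = FALSE]
  n_good <- max(1L, ceiling(gamma * nrow(ok)))
  ord <- order(ok$score)
  good <- ok[ord[seq_len(n_good)], , drop = FALSE]
  bad <- ok[ord[-seq_len(n_good)], , drop = FALSE]

  models <- lapply(space, function(def) {
    if (def$kind == "categorical") {
      tab_g <- table(factor(good[[def$name]], levels = as.character(def$choices)))
      tab_b <- table(factor(bad[[def$name]], levels = as.character(def$choices)))
      list(kind = "categorical",
           pg = (tab_g + 1) / sum(tab_g + 1),
           pb = (tab_b + 1) / sum(tab_b + 1), def = def)
    } else {
      tf <- if (isTRUE(def$log)) log else identity
      lo <- tf(def$lower); hi <- tf(def$upper)
      list(kind = def$kind, tf = tf, log = isTRUE(def$log),
           g = parzen_numeric(tf(as.numeric(good[[def$name]])), lo, hi),
           b = parzen_numeric(tf(as.numeric(bad[[def$name]])), lo, hi),
           def = def)
    }
  })

  best_score <- -Inf
  best_cand <- NULL
  for (c in seq_len(n_candidates)) {
    cand <- list()
    sc <- 0
    for (m in models) {
      if (m$kind == "categorical") {
        val <- as.character(parzen_sample_cat(m$pg))
        sc <- sc + log(m$pg[[val]]) - log(m$pb[[val]])
        ch <- m$def$choices
        cand[[m$def$name]] <- ch[[match(val, as.character(ch))]]
      } else {
        x <- parzen_sample(m$g)
        sc <- sc + log(parzen_density(m$g, x)) - log(parzen_density(m$b, x))
        val <- if (m$log) exp(x) else x
        if (m$kind == "integer") {
          val <- as.integer(round(min(m$def$upper, max(m$def$lower, val))))
        }
        cand[[m$def$name]] <- val
      }
    }
    if (sc > best_score) {
      best_score <- sc
      best_cand <- cand
    }
  }
  best_cand
}

parzen_sample_cat <- function(p) {
  names(p)[[sample.int(length(p), 1L, prob = as.numeric(p))]]
}

#' Bayesian (TPE) or random hyperparameter search
#'
#' Minimizes `objective(params)` over a [search_space()], evaluating at most
#' `n_iter` parameter settings. The `"tpe"` engine is a tree-structured
#' Parzen estimator: after `n_init` seeded random trials, completed trials
#' are split at the `gamma` quantile of the score into good/bad sets,
#' Parzen densities `l(x)` and `g(x)` are fitted per parameter, and the
#' candidate maximizing `l(x)/g(x)` among `n_candidates` draws from `l` is
#' evaluated next. The `"random"` engine draws every trial from the prior;
#' both engines share the result schema and are fully reproducible from the
#' seed. The search stops early when the incumbent best score has improved
#' by no more than `tol` over the last `window` trials.
#'
#' @param space a [search_space()].
#' @param objective function mapping a named parameter list to a numeric
#'   score (lower is better); an error inside the objective marks the trial
#'   failed and the search continues.
#' @param n_iter evaluation budget (default 100).
#' @param tol minimum incumbent improvement per `window` trials (default
#'   1e-5).
#' @param engine `"tpe"` (default) or `"random"`.
#' @param seed integer seed.
#' @param window sliding-window length for the stopping rule (default 10).
#' @param n_init random trials before the TPE model switches on.
#' @param gamma good/bad split quantile for TPE.
#' @return an object of class `tune_result`: `trials` (data.frame of
#'   parameters, `score`, `failed`), `best_parameters`, `best_score`,
#'   `stopped_reason` (`"budget"` or `"tolerance"`).
#' @export
tune <- function(space, objective, n_iter = 100, tol = 1e-5,
                 engine = c("tpe", "random"), seed = 1L, window = 10L,
                 n_init = 10L, gamma = 0.25) {
  engine <- match.arg(engine)
  stopifnot(inherits(space, "search_space"))
  trials <- NULL
  stopped <- "budget"
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      params <- if (engine == "random" || i <= n_init ||
                    sum(!trials$failed) < 2L) {
        lapply(space, sample_param)
      } else {
        tpe_suggest(space, trials, gamma = gamma)
      }
      names(params) <- names(space)
      score <- tryCatch(as.numeric(objective(params)),
                        error = function(e) NA_real_)
      failed <- !is.finite(score)
      row <- as.data.frame(params, stringsAsFactors = FALSE)
      row$score <- if (failed) NA_real_ else score
      row$failed <- failed
      trials <- rbind(trials, row)

      done <- which(!trials$failed)
      if (length(done) > 0L && i > window) {
        past <- trials$score[done[done <= i - window]]
        now_best <- min(trials$score[done])
        if (length(past) > 0L && (min(past) - now_best) <= tol) {
          stopped <- "tolerance"
          break
        }
      }
    }
  })
  done <- which(!trials$failed)
  if (length(done) == 0L) {
    stop_mtgwp("all trials failed", class = "mtgwp_run_error")
  }
  best_i <- done[which.min(trials$score[done])]
  best_parameters <- as.list(trials[best_i, names(space), drop = FALSE])
  structure(
    list(trials = trials, best_parameters = best_parameters,
         best_score = trials$score[best_i], best_index = best_i,
         stopped_reason = stopped),
    class = "tune_result"
  )
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("<tune_result> %d trials (%s), best score %.6g\n",
              nrow(x$trials), x$stopped_reason, x$best_score))
  invisible(x)
}

subset_rows <- function(Y, idx) {
  if (inherits(Y, "trait_data")) {
    if (Y$mode == "regression") {
      trait_data(Y$values[idx, , drop = FALSE], "regression", Y$trait_names)
    } else {
      trait_data(Y$values[idx], "classification", Y$trait_names, Y$n_classes)
    }
  } else if (is.matrix(Y)) {
    Y[idx, , drop = FALSE]
  } else {
    Y[idx]
  }
}

trait_labels <- function(Y) {
  if (inherits(Y, "trait_data") && Y$mode == "classification") {
    Y$values
  } else if (!is.matrix(Y) && !inherits(Y, "trait_data") &&
             all(as.numeric(Y) == round(as.numeric(Y)))) {
    as.integer(Y)
  } else {
    NULL
  }
}

#' k-fold cross-validation score on the training partition
#'
#' Assigns the training samples to `k_folds` folds (deterministically from
#' `seed`; stratified by class for classification targets), trains on the
#' complement of each fold, scores on the held-out fold, and returns the
#' mean of the fold scores. The test partition never enters: `cv_score`
#' only ever sees `train_idx`.
#'
#' @param trainer function `(X_train, Y_train, X_val, Y_val) -> score`
#'   (lower is better).
#' @param X full marker matrix (or [genotype_matrix()]).
#' @param Y full traits (matrix, labels, or [trait_data()]).
#' @param train_idx indices of the training partition.
#' @param k_folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return list with `mean_score` and the `fold_scores` vector.
#' @export
cv_score <- function(trainer, X, Y, train_idx, k_folds = 5L, seed = 1L) {
  if (inherits(X, "genotype_matrix")) X <- X$values
  n <- length(train_idx)
  if (n < k_folds) {
    stop_mtgwp("fewer training samples than folds",
               class = "mtgwp_precondition_error")
  }
  labels <- trait_labels(Y)
  folds <- with_seed(seed, {
    if (!is.null(labels)) {
      lab <- labels[train_idx]
      counts <- table(lab)
      if (any(counts < 2L)) {
        stop_mtgwp("class(es) with fewer than 2 training samples cannot be ",
                   "stratified across folds: ",
                   paste(names(counts)[counts < 2L], collapse = ", "),
                   class = "mtgwp_stratification_error")
      }
      f <- integer(n)
      for (cl in names(counts)) {
        pos <- which(lab == as.integer(cl))
        pos <- pos[sample.int(length(pos))]
        f[pos] <- rep_len(sample.int(k_folds), length(pos))
      }
      f
    } else {
      rep_len(sample.int(k_folds), n)[sample.int(n)]
    }
  })
  if (!is.null(labels)) {
    for (f in seq_len(k_folds)) {
      tr_lab <- labels[train_idx[folds != f]]
      if (length(unique(tr_lab)) < length(unique(labels[train_idx]))) {
        stop_mtgwp("fold ", f, " training data is missing a class",
                   class = "mtgwp_stratification_error")
      }
    }
  }
  fold_scores <- vapply(seq_len(k_folds), function(f) {
    va <- train_idx[folds == f]
    tr <- train_idx[folds != f]
    as.numeric(trainer(X[tr, , drop = FALSE], subset_rows(Y, tr),
                       X[va, , drop = FALSE], subset_rows(Y, va)))
  }, numeric(1))
  list(mean_score = mean(fold_scores), fold_scores = fold_scores)
}
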