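#' Benchmark run configuration
#'
#' @param dataset either a [sim_config()] (data simulated on the fly) or a
#'   named list `list(geno = path, pheno = path, coding = ...)` of delimited
#'   files.
#' @param models character vector among `"lassonet"`, `"gandalf"`, `"mlp"`,
#'   `"gbdt"`.
#' @param task `"regression"` or `"classification"`.
#' @param seeds integer seeds for the ensembling protocol (default `1:10`).
#' @param split_fractions train/validation/test fractions.
#' @param split_seed seed for the sample split.
#' @param model_params named list of per-model parameter lists (e.g.
#'   `list(lassonet = list(path_multiplier = 1.2))`).
#' @param outdir optional directory for the JSON report and logs.
#' @return an object of class `run_config`.
#' @export
run_config <- function(dataset, models = c("lassonet", "mlp"),
                       task = c("regression", "classification"),
                       seeds = 1:10, split_fractions = c(0.7, 0.1, 0.2),
                       split_seed = 1L, model_params = list(),
                       outdir = NULL) {
  task <- match.arg(task)
  known <- c("lassonet", "gandalf", "mlp", "gbdt")
  if (length(models) == 0L || !all(models %in% known)) {
    stop_mtgwp("models must be a non-empty subset of: ",
               paste(known, collapse = ", "), class = "mtgwp_config_error")
  }
  if (anyDuplicated(seeds)) {
    stop_mtgwp("seeds must be unique", class = "mtgwp_config_error")
  }
  structure(
    list(dataset = dataset, models = models, task = task,
         seeds = as.integer(seeds), split_fractions = split_fractions,
         split_seed = as.integer(split_seed), model_params = model_params,
         outdir = outdir),
    class = "run_config"
  )
}

benchmark_data <- function(config) {
  ds <- config$dataset
  if (inherits(ds, "sim_config")) {
    G <- simulate_genotypes(ds)
    if (anyNA(G$values)) G <- impute_marginal(G, seed = derive_seed(ds$seed, 3L))
    sim <- simulate_traits(G, ds)
    Y <- if (config$task == "classification") {
      liability_to_fourclass(sim$traits$values[, 1:2, drop = FALSE])
    } else {
      sim$traits
    }
    list(X = G, Y = Y, truth = sim$truth, n = nrow(G$values))
  } else {
    G <- read_genotypes(ds$geno, coding = ds$coding %||% "additive_012")
    Y <- read_traits(ds$pheno)
    list(X = G, Y = Y, truth = NULL, n = nrow(G$values))
  }
}

run_one_model <- function(model, X, Y, split, config, seed) {
  pars <- config$model_params[[model]] %||% list()
  task <- config$task
  switch(model,
    lassonet = {
      cfg_args <- modifyList(list(task = task, seed = seed), pars)
      lcfg <- do.call(lassonet_config, cfg_args)
      path <- fit_path(X, Y, split, lcfg, keep_theta = FALSE)
      best <- select_model(path)
      Xm <- if (inherits(X, "genotype_matrix")) X$values else as.matrix(X)
      preds <- if (task == "classification") {
        predict(best$model, Xm[split$test_idx, , drop = FALSE], type = "probs")
      } else {
        predict(best$model, Xm[split$test_idx, , drop = FALSE])
      }
      list(predictions = preds, extra = list(
        support = best$support, lambda = best$lambda,
        selected = selected_features(best$model)$counts))
    },
    gandalf = {
      cfg_args <- modifyList(list(task = task, seed = seed), pars)
      gcfg <- do.call(gandalf_config, cfg_args)
      model_fit <- fit_gandalf(X, Y, split, gcfg)
      Xm <- if (inherits(X, "genotype_matrix")) X$values else as.matrix(X)
      preds <- if (task == "classification") {
        predict(model_fit, Xm[split$test_idx, , drop = FALSE], type = "probs")
      } else {
        predict(model_fit, Xm[split$test_idx, , drop = FALSE])
      }
      list(predictions = preds, extra = NULL)
    },
    mlp = {
      fit <- fit_mlp_baseline(X, Y, split, pars, seed = seed, task = task)
      list(predictions = fit$predictions, extra = NULL)
    },
    gbdt = {
      fit <- fit_gbdt_baseline(X, Y, split, pars, seed = seed, task = task)
      list(predictions = fit$predictions, extra = NULL)
    }
  )
}

#' Run an end-to-end benchmark
#'
#' For each requested model: trains once per seed, forms the seed-ensemble
#' prediction, and evaluates the task's metrics on the untouched test
#' partition (mean and standard deviation across seeds plus the
#' ensemble-prediction metric). Per-model failures are recorded and the run
#' continues. The report carries provenance (an MD5 hash of the serialized
#' configuration and the seed list) sufficient to re-run it.
#'
#' @param config a [run_config()].
#' @return an object of class `benchmark_report`: per-model
#'   [ensemble_evaluate()] reports (or error messages), per-model extras
#'   (e.g. LassoNet selected-feature counts), and provenance.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dat <- benchmark_data(config)
  split <- split_data(dat$n, config$split_fractions, config$split_seed)
  Y_test <- if (config$task == "regression") {
    dat$Y$values[split$test_idx, , drop = FALSE]
  } else {
    dat$Y$values[split$test_idx]
  }

  results <- list()
  extras <- list()
  for (m in config$models) {
    res <- tryCatch({
      extra_env <- new.env()
      rep <- ensemble_evaluate(function(seed) {
        out <- run_one_model(m, dat$X, dat$Y, split, config, seed)
        if (!is.null(out$extra)) assign("extra", out$extra, envir = extra_env)
        out$predictions
      }, Y_test, task = config$task, seeds = config$seeds)
      extras[[m]] <- if (exists("extra", envir = extra_env)) {
        get("extra", envir = extra_env)
      } else NULL
      rep
    }, error = function(e) {
      structure(list(error = conditionMessage(e)), class = "benchmark_failure")
    })
    results[[m]] <- res
  }

  cfg_json <- jsonlite::toJSON(
    list(models = config$models, task = config$task, seeds = config$seeds,
         split_fractions = config$split_fractions,
         split_seed = config$split_seed,
         dataset = if (inherits(config$dataset, "sim_config")) {
           unclass(config$dataset)
         } else {
           config$dataset
         },
         model_params = config$model_params),
    auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)

  report <- structure(
    list(results = results, extras = extras, seeds = config$seeds,
         task = config$task,
         provenance = list(config_hash = hash, seeds = config$seeds,
                           package_version = as.character(
                             utils::packageVersion("mtgwp")))),
    class = "benchmark_report"
  )
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    strip_preds <- report
    for (m in names(strip_preds$results)) {
      strip_preds$results[[m]]$ensemble_prediction <- NULL
    }
    write_report(strip_preds, file.path(config$outdir, "benchmark_report.json"))
  }
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> task %s, %d seeds\n", x$task,
              length(x$seeds)))
  for (m in names(x$results)) {
    r <- x$results[[m]]
    if (inherits(r, "benchmark_failure")) {
      cat(sprintf("  %s: FAILED (%s)\n", m, r$error))
    } else {
      first <- names(r$mean)[1L]
      cat(sprintf("  %s: %s %.4g +/- %.4g (ensemble %.4g)\n", m, first,
                  r$mean[[first]], r$stddev[[first]], r$ensemble[[first]]))
    }
  }
  invisible(x)
}
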