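#' Simulation configuration for synthetic genotype-phenotype data
#'
#' Describes a synthetic SNP panel and multi-trait genetic architecture:
#' `n_samples` individuals genotyped at `n_markers` biallelic markers in
#' additive 0/1/2 dosage coding or dominant 0/1 presence coding, with minor
#' allele frequencies drawn from `maf_range`, blockwise linkage disequilibrium
#' (latent Gaussian AR(1) copula with correlation `ld_rho` inside blocks of
#' `ld_block_size` markers, independence across blocks), a sparse pleiotropic
#' QTL architecture (`n_qtl_shared` markers affecting every trait plus
#' `n_qtl_specific` private markers per trait, effect sizes N(0, effect_sd^2),
#' optionally `epistatic_pairs` pairwise product interactions), per-trait
#' narrow-sense heritability targets, and completely-at-random missingness.
#'
#' @param n_samples number of individuals (rows).
#' @param n_markers number of markers (columns).
#' @param n_traits number of continuous traits `k`.
#' @param coding `"additive_012"` (SNP dosage) or `"dominant_01"` (DArT-like
#'   presence/absence).
#' @param maf_range length-2 vector of allele frequencies in (0, 0.5];
#'   per-marker frequencies are drawn uniformly from this interval.
#' @param ld_block_size number of consecutive markers per LD block.
#' @param ld_rho latent AR(1) correlation inside a block, in \[0, 1).
#' @param n_qtl_shared number of causal markers shared by all traits.
#' @param n_qtl_specific number of causal markers private to each trait.
#' @param effect_sd scale of QTL effect sizes.
#' @param effect_dist `"fixed"` (default): every causal effect has magnitude
#'   `effect_sd` with an independent random sign — the equal-effects
#'   architecture standard for support-recovery studies, ensuring each
#'   planted QTL carries a detectable share of the genetic variance;
#'   `"normal"`: effects drawn N(0, effect_sd^2), which yields a long tail
#'   of near-zero effects no method can recover at moderate n.
#' @param epistatic_pairs number of pairwise (product) interaction terms.
#' @param heritability per-trait h2 in \[0, 1\]; recycled to `n_traits`.
#' @param missing_rate proportion of genotype entries set missing, in \[0, 1).
#' @param seed integer seed; all simulation is a pure function of
#'   (configuration, seed).
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500, n_markers = 2000, n_traits = 3,
                       coding = c("additive_012", "dominant_01"),
                       maf_range = c(0.05, 0.5), ld_block_size = 10,
                       ld_rho = 0.3, n_qtl_shared = 20, n_qtl_specific = 0,
                       effect_sd = 1, effect_dist = c("fixed", "normal"),
                       epistatic_pairs = 0,
                       heritability = 0.6, missing_rate = 0, seed = 1L) {
  coding <- match.arg(coding)
  effect_dist <- match.arg(effect_dist)
  if (!is_count(n_samples) || !is_count(n_markers) || !is_count(n_traits)) {
    stop_mtgwp("n_samples, n_markers and n_traits must be positive integers",
               class = "mtgwp_config_error")
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop_mtgwp("maf_range must be an ordered pair of frequencies in (0, 0.5]",
               class = "mtgwp_config_error")
  }
  if (ld_rho < 0 || ld_rho >= 1) {
    stop_mtgwp("ld_rho must lie in [0, 1)", class = "mtgwp_config_error")
  }
  if (!is_count(ld_block_size)) {
    stop_mtgwp("ld_block_size must be a positive integer",
               class = "mtgwp_config_error")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_mtgwp("missing_rate must lie in [0, 1)", class = "mtgwp_config_error")
  }
  heritability <- rep_len(heritability, n_traits)
  if (any(heritability < 0 | heritability > 1)) {
    stop_mtgwp("heritability values must lie in [0, 1]",
               class = "mtgwp_config_error")
  }
  if (n_qtl_shared + n_traits * n_qtl_specific > n_markers) {
    stop_mtgwp("n_qtl_shared + n_traits * n_qtl_specific exceeds n_markers",
               class = "mtgwp_config_error")
  }
  structure(
    list(n_samples = as.integer(n_samples), n_markers = as.integer(n_markers),
         n_traits = as.integer(n_traits), coding = coding,
         maf_range = as.numeric(maf_range),
         ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
         n_qtl_shared = as.integer(n_qtl_shared),
         n_qtl_specific = as.integer(n_qtl_specific), effect_sd = effect_sd,
         effect_dist = effect_dist,
         epistatic_pairs = as.integer(epistatic_pairs),
         heritability = heritability, missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Construct a genotype matrix object
#'
#' @param values integer matrix (samples x markers); `NA` marks missing calls.
#' @param sample_ids,marker_ids unique identifiers; default to the matrix
#'   dimnames when present, else `S1..Sn` / `M1..Mp`.
#' @param coding `"additive_012"` or `"dominant_01"`.
#' @return an object of class `genotype_matrix` with fields `values`,
#'   `sample_ids`, `marker_ids`, `coding`.
#' @export
genotype_matrix <- function(values, sample_ids = NULL, marker_ids = NULL,
                            coding = c("additive_012", "dominant_01")) {
  coding <- match.arg(coding)
  values <- as.matrix(values)
  sample_ids <- sample_ids %||% rownames(values) %||%
    paste0("S", seq_len(nrow(values)))
  marker_ids <- marker_ids %||% colnames(values) %||%
    paste0("M", seq_len(ncol(values)))
  storage.mode(values) <- "integer"
  if (anyDuplicated(sample_ids) || anyDuplicated(marker_ids)) {
    stop_mtgwp("sample and marker identifiers must be unique",
               class = "mtgwp_data_error")
  }
  if (length(sample_ids) != nrow(values) || length(marker_ids) != ncol(values)) {
    stop_mtgwp("identifier lengths do not match matrix dimensions",
               class = "mtgwp_data_error")
  }
  codes <- if (coding == "additive_012") 0:2 else 0:1
  bad <- !is.na(values) & !(values %in% codes)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop_mtgwp("invalid genotype code ", values[bad][1L], " at sample ",
               sample_ids[idx[1L]], ", marker ", marker_ids[idx[2L]],
               " for coding ", coding, class = "mtgwp_data_error")
  }
  dimnames(values) <- list(sample_ids, marker_ids)
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 marker_ids = as.character(marker_ids), coding = coding),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$values))
  cat(sprintf("<genotype_matrix> %d samples x %d markers, coding %s, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$coding, 100 * miss))
  invisible(x)
}

#' Construct a trait data object
#'
#' @param values numeric matrix (regression, samples x traits) or an integer
#'   label vector in `0..n_classes-1` (classification).
#' @param mode `"regression"` or `"classification"`.
#' @param trait_names trait (or class-label column) names.
#' @param n_classes number of classes `K` (classification only).
#' @return an object of class `trait_data`.
#' @export
trait_data <- function(values, mode = c("regression", "classification"),
                       trait_names = NULL, n_classes = NULL) {
  mode <- match.arg(mode)
  if (mode == "regression") {
    values <- as.matrix(values)
    if (!all(is.finite(values))) {
      stop_mtgwp("regression trait values must be finite",
                 class = "mtgwp_data_error")
    }
    trait_names <- trait_names %||% colnames(values) %||%
      paste0("T", seq_len(ncol(values)))
    colnames(values) <- trait_names
    structure(list(mode = mode, values = values,
                   trait_names = as.character(trait_names)),
              class = "trait_data")
  } else {
    values <- as.integer(values)
    n_classes <- as.integer(n_classes %||% (max(values) + 1L))
    if (any(values < 0L) || any(values >= n_classes)) {
      stop_mtgwp("class labels must lie in 0..K-1", class = "mtgwp_data_error")
    }
    trait_names <- trait_names %||% "class"
    structure(list(mode = mode, values = values,
                   trait_names = as.character(trait_names),
                   n_classes = n_classes),
              class = "trait_data")
  }
}

#' @export
print.trait_data <- function(x, ...) {
  if (x$mode == "regression") {
    cat(sprintf("<trait_data> regression, %d samples x %d traits (%s)\n",
                nrow(x$values), ncol(x$values),
                paste(x$trait_names, collapse = ", ")))
  } else {
    cat(sprintf("<trait_data> classification, %d samples, %d classes\n",
                length(x$values), x$n_classes))
  }
  invisible(x)
}

#' Simulate genotypes with blockwise linkage disequilibrium
#'
#' Marker allele frequencies are drawn uniformly from `config$maf_range`.
#' Haplotypes arise from a latent Gaussian AR(1) process within LD blocks
#' (correlation `ld_rho`, independence across blocks) thresholded at the
#' allele-frequency quantile; additive genotypes sum two independent
#' haplotypes (0/1/2), dominant genotypes use a single haplotype (0/1).
#' Realized adjacent-marker genotype correlation is attenuated relative to the
#' latent `ld_rho` by the thresholding, as with any discretized copula.
#' Missing entries are introduced completely at random at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples; p <- config$n_markers
  with_seed(config$seed, {
    freqs <- runif(p, config$maf_range[1], config$maf_range[2])
    n_hap <- if (config$coding == "additive_012") 2L else 1L
    G <- matrix(0L, n, p)
    starts <- seq(1L, p, by = config$ld_block_size)
    for (h in seq_len(n_hap)) {
      Z <- matrix(0, n, p)
      rho <- config$ld_rho
      for (s in starts) {
        e <- min(s + config$ld_block_size - 1L, p)
        Z[, s] <- rnorm(n)
        if (e > s) {
          for (j in (s + 1L):e) {
            Z[, j] <- rho * Z[, j - 1L] + sqrt(1 - rho^2) * rnorm(n)
          }
        }
      }
      G <- G + (Z < rep(qnorm(freqs), each = n))
    }
    storage.mode(G) <- "integer"
    if (config$missing_rate > 0) {
      G[runif(n * p) < config$missing_rate] <- NA_integer_
    }
    genotype_matrix(G, coding = config$coding)
  })
}

#' Simulate multi-trait phenotypes with a sparse pleiotropic QTL architecture
#'
#' Phenotypes follow `Y = Z beta + epistasis + e` where `Z` is the
#' column-standardized genotype matrix. `n_qtl_shared` markers carry one
#' effect shared identically by all traits (pleiotropy, inducing genetic
#' correlation between traits); `n_qtl_specific` further markers per trait
#' carry private effects; optional epistatic terms are products of two
#' standardized causal markers assigned to a random trait. Per trait, the
#' noise variance is set so that var(genetic) / var(total) equals the target
#' heritability; the returned traits are z-scored on the full sample. With
#' `h2 = 1` the traits are exactly the standardized genetic values; with
#' `h2 = 0` the genetic term is dropped and traits are pure standardized noise.
#'
#' @param G a complete (no missing calls) [genotype_matrix()].
#' @param config the [sim_config()] used to generate `G` (its seed is offset
#'   internally so genotype and trait draws are independent streams).
#' @return a list with elements `traits` (a [trait_data()], regression mode)
#'   and `truth` (class `qtl_truth`: per-trait causal marker indices, the
#'   `p x k` effect matrix on the standardized scale, epistatic terms, and the
#'   per-trait genetic-variance fractions actually realized).
#' @export
simulate_traits <- function(G, config) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(config, "sim_config"))
  if (anyNA(G$values)) {
    stop_mtgwp("genotypes contain missing calls; impute before simulating traits",
               class = "mtgwp_precondition_error")
  }
  n <- nrow(G$values); p <- ncol(G$values); k <- config$n_traits
  with_seed(derive_seed(config$seed, 7L), {
    Z <- scale(G$values)
    Z[, attr(Z, "scaled:scale") == 0 | !is.finite(attr(Z, "scaled:scale"))] <- 0
    Z <- matrix(as.numeric(Z), n, p)

    draw_effects <- function(m) {
      if ((config$effect_dist %||% "fixed") == "fixed") {
        config$effect_sd * sample(c(-1, 1), m, replace = TRUE)
      } else {
        rnorm(m, 0, config$effect_sd)
      }
    }
    n_causal <- config$n_qtl_shared + k * config$n_qtl_specific
    causal_all <- sample.int(p, n_causal)
    shared_idx <- causal_all[seq_len(config$n_qtl_shared)]
    specific_idx <- vector("list", k)
    pos <- config$n_qtl_shared
    beta <- matrix(0, p, k)
    shared_eff <- draw_effects(config$n_qtl_shared)
    for (t in seq_len(k)) {
      beta[shared_idx, t] <- shared_eff
      if (config$n_qtl_specific > 0L) {
        idx <- causal_all[pos + seq_len(config$n_qtl_specific)]
        pos <- pos + config$n_qtl_specific
        specific_idx[[t]] <- idx
        beta[idx, t] <- draw_effects(config$n_qtl_specific)
      } else {
        specific_idx[[t]] <- integer(0)
      }
    }

    Gval <- Z %*% beta
    epi <- list()
    if (config$epistatic_pairs > 0L && length(shared_idx) >= 2L) {
      for (e in seq_len(config$epistatic_pairs)) {
        pair <- sample(causal_all, 2L)
        tr <- sample.int(k, 1L)
        coefficient <- draw_effects(1L)
        Gval[, tr] <- Gval[, tr] + coefficient * Z[, pair[1]] * Z[, pair[2]]
        epi[[e]] <- list(marker_i = pair[1], marker_j = pair[2],
                         trait = tr, coefficient = coefficient)
      }
    }

    Y <- matrix(0, n, k)
    realized_h2 <- numeric(k)
    for (t in seq_len(k)) {
      h2 <- config$heritability[t]
      vg <- var(Gval[, t])
      if (h2 >= 1) {
        y <- Gval[, t]
      } else if (h2 <= 0 || vg == 0) {
        y <- rnorm(n)
        realized_h2[t] <- 0
      } else {
        e <- rnorm(n, 0, sqrt(vg * (1 - h2) / h2))
        y <- Gval[, t] + e
      }
      if (h2 > 0 && vg > 0) realized_h2[t] <- vg / var(y)
      Y[, t] <- if (sd(y) > 0) (y - mean(y)) / sd(y) else y
    }

    causal_indices <- lapply(seq_len(k), function(t) {
      sort(unique(c(shared_idx, specific_idx[[t]])))
    })
    truth <- structure(
      list(causal_indices = causal_indices, effects = beta,
           shared_indices = sort(shared_idx), epistatic_terms = epi,
           realized_h2 = realized_h2),
      class = "qtl_truth"
    )
    list(traits = trait_data(Y, "regression"), truth = truth)
  })
}

#' Recode two liability-scale traits into four classes
#'
#' Each of the two continuous columns (e.g. deregressed breeding values) is
#' thresholded at zero into a binary trait (strictly greater than 0 maps to 1,
#' anything else — including exactly 0 — to 0); the binary pair `(b1, b2)`
#' becomes the class label `2*b1 + b2`, i.e. `(0,0) -> 0`, `(0,1) -> 1`,
#' `(1,0) -> 2`, `(1,1) -> 3`.
#'
#' @param Y2 an `n x 2` numeric matrix, or a regression [trait_data()] with
#'   exactly two traits.
#' @return a classification [trait_data()] with `n_classes = 4`.
#' @seealso [fourclass_to_binary()] for the inverse label mapping.
#' @export
liability_to_fourclass <- function(Y2) {
  if (inherits(Y2, "trait_data")) {
    if (Y2$mode != "regression") {
      stop_mtgwp("expected continuous traits", class = "mtgwp_precondition_error")
    }
    Y2 <- Y2$values
  }
  Y2 <- as.matrix(Y2)
  if (ncol(Y2) != 2L) {
    stop_mtgwp("four-class recoding requires exactly 2 trait columns, got ",
               ncol(Y2), class = "mtgwp_precondition_error")
  }
  b <- (Y2 > 0) * 1L
  trait_data(2L * b[, 1L] + b[, 2L], "classification", n_classes = 4L)
}

#' Invert the four-class recoding back to the binary trait pair
#'
#' @param labels integer labels in `0..3` (or a classification [trait_data()]).
#' @return an `n x 2` integer matrix of binary traits.
#' @export
fourclass_to_binary <- function(labels) {
  if (inherits(labels, "trait_data")) labels <- labels$values
  labels <- as.integer(labels)
  if (any(labels < 0L | labels > 3L)) {
    stop_mtgwp("labels must lie in 0..3", class = "mtgwp_precondition_error")
  }
  cbind(b1 = labels %/% 2L, b2 = labels %% 2L)
}

#' Filter markers by minor allele frequency
#'
#' The allele-dosage frequency of a marker is its mean non-missing code
#' divided by the maximum dosage (2 for additive coding, 1 for dominant);
#' MAF is `min(f, 1 - f)`. Markers with MAF strictly below `threshold` are
#' removed (the conventional quality-control step before genomic prediction).
#'
#' @param G a [genotype_matrix()].
#' @param threshold MAF threshold in \[0, 0.5\]; default 0.05.
#' @return a list with `genotypes` (filtered [genotype_matrix()]) and
#'   `removed` (character vector of removed marker ids).
#' @export
maf_filter <- function(G, threshold = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (threshold < 0 || threshold > 0.5) {
    stop_mtgwp("threshold must lie in [0, 0.5]", class = "mtgwp_config_error")
  }
  max_dose <- if (G$coding == "additive_012") 2 else 1
  f <- colMeans(G$values, na.rm = TRUE) / max_dose
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & maf >= threshold
  removed <- G$marker_ids[!keep]
  if (!any(keep)) {
    warning("all markers fall below the MAF threshold; returning empty matrix")
    return(list(
      genotypes = genotype_matrix(G$values[, 0, drop = FALSE],
                                  sample_ids = G$sample_ids,
                                  marker_ids = character(0), coding = G$coding),
      removed = removed
    ))
  }
  list(
    genotypes = genotype_matrix(G$values[, keep, drop = FALSE],
                                sample_ids = G$sample_ids,
                                marker_ids = G$marker_ids[keep],
                                coding = G$coding),
    removed = removed
  )
}

#' Impute missing genotypes from each marker's marginal distribution
#'
#' Every missing call is replaced by an independent draw from the empirical
#' distribution of that marker's observed codes.
#'
#' @param G a [genotype_matrix()].
#' @param seed integer seed making the imputation reproducible.
#' @return a complete [genotype_matrix()].
#' @export
impute_marginal <- function(G, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  V <- G$values
  miss_per_marker <- colSums(is.na(V))
  if (!any(miss_per_marker > 0L)) return(G)
  fully_missing <- miss_per_marker == nrow(V)
  if (any(fully_missing)) {
    stop_mtgwp("marker(s) with no observed genotypes cannot be imputed: ",
               paste(G$marker_ids[fully_missing], collapse = ", "),
               class = "mtgwp_data_error")
  }
  with_seed(seed, {
    for (j in which(miss_per_marker > 0L)) {
      obs <- V[!is.na(V[, j]), j]
      na_idx <- which(is.na(V[, j]))
      V[na_idx, j] <- sample(obs, length(na_idx), replace = TRUE)
    }
  })
  genotype_matrix(V, sample_ids = G$sample_ids, marker_ids = G$marker_ids,
                  coding = G$coding)
}

#' Partition samples into training, validation and test sets
#'
#' Validation and test sizes are `round(n * fraction)`; the remainder goes to
#' the training partition (deterministic tie-break). The default 70/10/20
#' split is the standard protocol for genomic-prediction benchmarks.
#'
#' @param n number of samples.
#' @param fractions length-3 vector `(train, validation, test)` summing to 1.
#' @param seed integer seed for the permutation.
#' @return an object of class `data_split` with disjoint covering index sets
#'   `train_idx`, `val_idx`, `test_idx` and the `fractions` used.
#' @export
split_data <- function(n, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  if (!is_count(n)) stop_mtgwp("n must be a positive integer",
                               class = "mtgwp_config_error")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9 ||
      any(fractions < 0)) {
    stop_mtgwp("fractions must be three non-negative values summing to 1",
               class = "mtgwp_config_error")
  }
  n_val <- round(n * fractions[2])
  n_test <- round(n * fractions[3])
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1L) {
    stop_mtgwp("split produces an empty partition (n = ", n, ")",
               class = "mtgwp_config_error")
  }
  with_seed(seed, {
    perm <- sample.int(n)
    structure(
      list(train_idx = sort(perm[seq_len(n_train)]),
           val_idx = sort(perm[n_train + seq_len(n_val)]),
           test_idx = sort(perm[n_train + n_val + seq_len(n_test)]),
           fractions = fractions),
      class = "data_split"
    )
  })
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> train %d / validation %d / test %d\n",
              length(x$train_idx), length(x$val_idx), length(x$test_idx)))
  invisible(x)
}
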