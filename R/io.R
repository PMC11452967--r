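# Delimited-text dialect: genotype and phenotype tables are CSV/TSV with a
# header row; the first column holds sample ids, remaining columns marker ids
# (genotypes) or trait names / a single "class" column (phenotypes); missing
# genotype calls are written as "NA". A sidecar JSON manifest can record the
# coding, seed, simulation truth and split indices.

#' Read a genotype matrix from delimited text
#'
#' @param path CSV/TSV file (dialect above; delimiter auto-detected).
#' @param coding expected marker coding, `"additive_012"` or `"dominant_01"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, coding = c("additive_012", "dominant_01")) {
  coding <- match.arg(coding)
  if (!file.exists(path)) {
    stop_mtgwp("file not found: ", path, class = "mtgwp_parse_error")
  }
  dt <- data.table::fread(path, header = TRUE, na.strings = "NA",
                          colClasses = list(character = 1L), showProgress = FALSE)
  if (ncol(dt) < 2L) {
    stop_mtgwp("malformed header in ", path,
               ": need a sample-id column plus marker columns",
               class = "mtgwp_parse_error")
  }
  sample_ids <- dt[[1L]]
  marker_ids <- names(dt)[-1L]
  codes <- if (coding == "additive_012") 0:2 else 0:1
  V <- matrix(NA_integer_, nrow(dt), length(marker_ids))
  for (j in seq_along(marker_ids)) {
    col <- dt[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which((!is.na(col) & is.na(num)) |
                   (!is.na(num) & (num != round(num) | !(num %in% codes))))
    if (length(bad) > 0L) {
      stop_mtgwp("invalid genotype code '", as.character(col[bad[1L]]),
                 "' for coding ", coding, " at line ", bad[1L] + 1L,
                 ", marker ", marker_ids[j], class = "mtgwp_parse_error")
    }
    V[, j] <- as.integer(num)
  }
  genotype_matrix(V, sample_ids = sample_ids, marker_ids = marker_ids,
                  coding = coding)
}

#' Write a genotype matrix to delimited text
#'
#' @param G a [genotype_matrix()].
#' @param path output file; a `.tsv` extension writes tab-separated.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  dt <- data.table::data.table(sample_id = G$sample_ids)
  dt <- cbind(dt, data.table::as.data.table(G$values))
  data.table::setnames(dt, c("sample_id", G$marker_ids))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(dt, path, sep = sep, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read trait data from delimited text
#'
#' A single trait column named `class` is read as multi-class labels;
#' anything else as continuous traits.
#'
#' @param path CSV/TSV file (first column sample ids).
#' @return a [trait_data()].
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) {
    stop_mtgwp("file not found: ", path, class = "mtgwp_parse_error")
  }
  dt <- data.table::fread(path, header = TRUE, na.strings = "NA",
                          colClasses = list(character = 1L), showProgress = FALSE)
  if (ncol(dt) < 2L) {
    stop_mtgwp("malformed header in ", path,
               ": need a sample-id column plus trait columns",
               class = "mtgwp_parse_error")
  }
  vals <- as.matrix(dt[, -1L])
  if (identical(names(dt)[-1L], "class")) {
    lab <- vals[, 1L]
    if (anyNA(lab) || any(lab != round(lab)) || any(lab < 0)) {
      stop_mtgwp("class labels must be non-negative integers (line ",
                 which(is.na(lab) | lab != round(lab) | lab < 0)[1L] + 1L, ")",
                 class = "mtgwp_parse_error")
    }
    trait_data(as.integer(lab), "classification")
  } else {
    if (anyNA(vals)) {
      stop_mtgwp("missing trait values at line ",
                 which(apply(is.na(vals), 1L, any))[1L] + 1L,
                 class = "mtgwp_parse_error")
    }
    storage.mode(vals) <- "double"
    rownames(vals) <- NULL
    trait_data(vals, "regression", trait_names = names(dt)[-1L])
  }
}

#' Write trait data to delimited text
#'
#' @param Y a [trait_data()].
#' @param path output file.
#' @param sample_ids optional sample identifiers for the first column.
#' @return `path`, invisibly.
#' @export
write_traits <- function(Y, path, sample_ids = NULL) {
  stopifnot(inherits(Y, "trait_data"))
  n <- if (Y$mode == "regression") nrow(Y$values) else length(Y$values)
  dt <- data.table::data.table(sample_id = sample_ids %||% paste0("S", seq_len(n)))
  if (Y$mode == "regression") {
    dt <- cbind(dt, data.table::as.data.table(Y$values))
    data.table::setnames(dt, c("sample_id", Y$trait_names))
  } else {
    dt[["class"]] <- Y$values
  }
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(dt, path, sep = sep, na = "NA", quote = FALSE)
  invisible(path)
}

#' Write a simulation manifest as JSON
#'
#' Sidecar metadata making a written dataset reproducible: coding, seed,
#' simulation ground truth (causal indices and effects) and split indices.
#'
#' @param path output JSON file.
#' @param coding marker coding string.
#' @param seed integer seed used.
#' @param truth optional `qtl_truth`.
#' @param split optional [split_data()] result.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, coding, seed, truth = NULL, split = NULL) {
  obj <- list(coding = coding, seed = seed)
  if (!is.null(truth)) {
    obj$truth <- list(causal_indices = truth$causal_indices,
                      shared_indices = truth$shared_indices,
                      effects = truth$effects,
                      realized_h2 = truth$realized_h2)
  }
  if (!is.null(split)) {
    obj$split <- list(train_idx = split$train_idx, val_idx = split$val_idx,
                      test_idx = split$test_idx, fractions = split$fractions)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a benchmark or metrics report as JSON
#'
#' @param report a `benchmark_report`, `metrics_report`, or plain list.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(path)
}
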