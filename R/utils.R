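#' @useDynLib mtgwp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor optimize predict qnorm quantile rbinom rnorm runif sd var
#' @importFrom utils head modifyList
NULL

# Run `expr` under a local RNG stream derived from `seed`, restoring the
# caller's RNG state afterwards. All stochastic operations in the package go
# through this so that results are pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and a stream index, staying inside the
# 32-bit signed integer range set.seed() accepts.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 1103515245 * as.double(stream)) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mtgwp <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "mtgwp_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
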