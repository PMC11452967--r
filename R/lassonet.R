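#' LassoNet training configuration
#'
#' Hyperparameters for the multi-task LassoNet: a residual network
#' `y = theta' x + g_W(x)` whose linear skip connection carries an L1 penalty
#' `lambda` while the hierarchy constraint
#' `||W_i^(1)||_inf <= nu * sel(theta_i)` ties the first-hidden-layer weights
#' of feature `i` to its skip coefficients, so a feature can only act
#' non-linearly if it is active linearly. `nu = 0` reduces the model to the
#' Lasso; `nu = Inf` removes the constraint and recovers a plain feed-forward
#' network.
#'
#' @param hidden_sizes integer vector of hidden-layer widths; `NULL` selects
#'   one hidden layer of width `min(100, ceiling(p/3))`.
#' @param nu hierarchy coefficient (a.k.a. `M`), `>= 0` or `Inf`.
#' @param path_multiplier geometric factor (> 1) by which `lambda` grows
#'   between path steps.
#' @param lambda_start first penalty on the path, or `"auto"` to choose the
#'   largest value whose first proximal application drops fewer than 5% of
#'   features.
#' @param epochs_dense maximum epochs for the dense (`lambda = 0`) warm start.
#' @param epochs_per_step gradient epochs per path step.
#' @param learning_rate step size for both phases.
#' @param momentum classical momentum for the path optimizer (set 0 for plain
#'   proximal gradient steps).
#' @param batch_size mini-batch size; `Inf` uses full-batch gradients.
#' @param patience early-stopping patience (epochs without validation
#'   improvement) for the dense phase.
#' @param seed integer seed controlling initialization and batch order.
#' @param task `"regression"` (k continuous traits) or `"classification"`
#'   (K classes, k = K logits).
#' @param standardize center/scale marker columns using training-partition
#'   statistics before fitting (recommended for dosage data).
#' @param optimizer_dense `"adam"` (default) or `"sgdm"` for the dense phase;
#'   path steps always use stochastic gradient descent with momentum, matching
#'   the proximal-gradient theory.
#' @param penalty multi-task selection convention: `"elementwise"` (penalty
#'   `sum_t |theta_it|`, constraint scale `max_t |theta_it|`; default) or
#'   `"grouped"` (penalty and scale `||theta_i||_2`).
#' @param freeze_dropped once a feature's skip row reaches zero on the path,
#'   keep it at zero (makes support monotonicity structural).
#' @param inner_tol optional convergence tolerance on the mean absolute
#'   `theta` update within a path step; when set, a step may finish before
#'   `epochs_per_step` epochs (full-batch mode).
#' @param max_steps upper bound on the number of path steps.
#'
#' @return an object of class `lassonet_config`.
#' @export
lassonet_config <- function(hidden_sizes = NULL, nu = 10,
                            path_multiplier = 1.02, lambda_start = "auto",
                            epochs_dense = 200, epochs_per_step = 10,
                            learning_rate = 0.01, momentum = 0.9,
                            batch_size = 64, patience = 10, seed = 1L,
                            task = c("regression", "classification"),
                            standardize = TRUE,
                            optimizer_dense = c("adam", "sgdm"),
                            penalty = c("elementwise", "grouped"),
                            freeze_dropped = TRUE, inner_tol = NULL,
                            max_steps = 1000L) {
  task <- match.arg(task)
  optimizer_dense <- match.arg(optimizer_dense)
  penalty <- match.arg(penalty)
  if (path_multiplier <= 1) {
    stop_mtgwp("path_multiplier must exceed 1", class = "mtgwp_config_error")
  }
  if (nu < 0) stop_mtgwp("nu must be >= 0", class = "mtgwp_config_error")
  structure(
    list(hidden_sizes = hidden_sizes, nu = nu,
         path_multiplier = path_multiplier, lambda_start = lambda_start,
         epochs_dense = as.integer(epochs_dense),
         epochs_per_step = as.integer(epochs_per_step),
         learning_rate = learning_rate, momentum = momentum,
         batch_size = batch_size, patience = as.integer(patience),
         seed = as.integer(seed), task = task, standardize = standardize,
         optimizer_dense = optimizer_dense, penalty = penalty,
         freeze_dropped = freeze_dropped, inner_tol = inner_tol,
         max_steps = as.integer(max_steps)),
    class = "lassonet_config"
  )
}

# ---- internal network machinery ------------------------------------------

ln_init_params <- function(p, k, hidden_sizes, seed) {
  with_seed(seed, {
    sizes <- c(p, hidden_sizes, k)
    layers <- vector("list", length(sizes) - 1L)
    for (l in seq_along(layers)) {
      fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
      s <- sqrt(6 / (fan_in + fan_out))
      layers[[l]] <- list(W = matrix(runif(fan_in * fan_out, -s, s),
                                     fan_in, fan_out),
                          b = numeric(fan_out))
    }
    list(theta = matrix(0, p, k), layers = layers)
  })
}

# Forward pass on already-standardized inputs. Hidden layers use the
# rectifier; the output layer is linear (regression traits or class logits)
# and is added to the linear skip term Z %*% theta.
ln_forward_raw <- function(par, Z, keep_cache = FALSE) {
  A <- Z
  L <- length(par$layers)
  cache <- if (keep_cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    lay <- par$layers[[l]]
    pre <- A %*% lay$W + rep(lay$b, each = nrow(A))
    if (keep_cache) cache[[l]] <- list(input = A, pre = pre)
    A <- if (l < L) relu(pre) else pre
  }
  out <- A + Z %*% par$theta
  if (keep_cache) list(out = out, cache = cache) else out
}

# Training loss and exact gradients for all parameters (backpropagation).
ln_loss_grad <- function(par, Z, Y, task) {
  fw <- ln_forward_raw(par, Z, keep_cache = TRUE)
  ld <- loss_and_dout(fw$out, Y, task)
  L <- length(par$layers)
  gl <- vector("list", L)
  d <- ld$dout
  gtheta <- crossprod(Z, d)
  for (l in rev(seq_len(L))) {
    cc <- fw$cache[[l]]
    if (l < L) d <- d * (cc$pre > 0)
    gl[[l]] <- list(W = crossprod(cc$input, d), b = colSums(d))
    if (l > 1L) d <- d %*% t(par$layers[[l]]$W)
  }
  list(loss = ld$loss, grad = list(theta = gtheta, layers = gl))
}

ln_val_loss <- function(par, Z, Y, task) {
  loss_and_dout(ln_forward_raw(par, Z), Y, task)$loss
}

as_xy <- function(X, Y, task) {
  if (inherits(X, "genotype_matrix")) X <- X$values
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (inherits(Y, "trait_data")) {
    if ((Y$mode == "regression") != (task == "regression")) {
      stop_mtgwp("task '", task, "' does not match trait data mode '",
                 Y$mode, "'", class = "mtgwp_precondition_error")
    }
    Y <- Y$values
  }
  if (task == "regression") {
    Y <- as.matrix(Y)
    list(X = X, Y = Y, k = ncol(Y))
  } else {
    Y <- as.integer(Y)
    list(X = X, Y = Y, k = max(Y) + 1L)
  }
}

standardize_fit <- function(X, idx, standardize) {
  if (!standardize) {
    return(list(center = rep(0, ncol(X)), scale = rep(1, ncol(X))))
  }
  center <- colMeans(X[idx, , drop = FALSE])
  scale <- apply(X[idx, , drop = FALSE], 2L, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(center = center, scale = scale)
}

apply_standardize <- function(X, st) {
  sweep(sweep(X, 2L, st$center, "-"), 2L, st$scale, "/")
}

make_batches <- function(n, batch_size) {
  if (!is.finite(batch_size) || batch_size >= n) return(list(seq_len(n)))
  perm <- sample.int(n)
  split(perm, ceiling(seq_along(perm) / batch_size))
}

# ---- hierarchical proximal operator --------------------------------------

#' Hierarchical proximal operator for one feature row
#'
#' Exact minimizer of
#' `0.5 * ||theta - b||^2 + 0.5 * ||w - v||^2 + lambda_step * pen(theta)`
#' subject to `||w||_inf <= nu * sel(theta)`, where `(b, v)` are a feature's
#' post-gradient skip coefficients and first-hidden-layer weights. Under the
#' `"elementwise"` convention `pen` is the elementwise L1 norm and `sel` the
#' max-abs over traits; under `"grouped"` both are the Euclidean row norm.
#' The solution combines soft-thresholding
#' `S(x) = sign(x) * max(|x| - lambda, 0)` of the skip row with clamping of
#' the hidden weights, coupled through a one-dimensional convex search over
#' the selection magnitude solved by a sorted breakpoint sweep in
#' `O((h + k) log(h + k))`. If the returned skip row is zero the returned
#' hidden row is zero, so skip sparsity controls feature sparsity exactly.
#'
#' @param theta_row numeric k-vector `b`.
#' @param w_row numeric h-vector `v`.
#' @param lambda_step penalty threshold (`lambda * learning_rate` inside a
#'   proximal gradient step), `>= 0`.
#' @param nu hierarchy coefficient, `>= 0` or `Inf` (unconstrained).
#' @param convention `"elementwise"` (default) or `"grouped"`.
#' @return list with components `theta` (k-vector) and `w` (h-vector).
#' @export
hier_prox <- function(theta_row, w_row, lambda_step, nu,
                      convention = c("elementwise", "grouped")) {
  convention <- match.arg(convention)
  stopifnot(lambda_step >= 0, nu >= 0)
  res <- prox_rows(matrix(as.numeric(theta_row), nrow = 1L),
                   matrix(as.numeric(w_row), nrow = 1L),
                   lambda_step, nu, convention = convention)
  list(theta = drop(res$theta), w = drop(res$w))
}

# Matrix form over all p feature rows; `active` freezes dropped rows at zero.
prox_rows <- function(Theta, W1, lambda_step, nu, active = NULL,
                      convention = "elementwise") {
  p <- nrow(Theta)
  if (is.null(active)) active <- rep(TRUE, p)
  if (convention == "elementwise") {
    hier_prox_matrix_cpp(Theta, W1, lambda_step, nu, active)
  } else {
    norms <- sqrt(rowSums(Theta^2))
    res <- hier_prox_matrix_cpp(matrix(norms, ncol = 1L), W1, lambda_step, nu,
                                active)
    mags <- drop(res$theta)
    scl <- ifelse(norms > 0, mags / norms, 0)
    list(theta = Theta * scl, w = res$w)
  }
}

# ---- training ------------------------------------------------------------

check_finite_loss <- function(loss, lr) {
  if (!is.finite(loss)) {
    stop_mtgwp("training diverged (non-finite loss) at learning rate ", lr,
               "; reduce learning_rate", class = "mtgwp_divergence_error")
  }
}

#' Train the dense (lambda = 0) LassoNet model
#'
#' Fits the unpenalized residual network by mini-batch gradient descent on
#' the multivariate loss (mean squared error over traits, or softmax
#' cross-entropy over classes), with early stopping on the validation
#' partition. This is the warm start from which [fit_path()] begins the
#' dense-to-sparse regularization path; with `nu = Inf` it is also the plain
#' multi-task MLP baseline.
#'
#' @param X `n x p` marker matrix (numeric matrix or [genotype_matrix()]).
#' @param Y traits: numeric `n x k` matrix or labels in `0..K-1`, or a
#'   [trait_data()].
#' @param split a [split_data()] result; training uses `train_idx`, early
#'   stopping monitors `val_idx`.
#' @param config a [lassonet_config()].
#' @param init optional initial parameters (as produced internally); used
#'   e.g. to study permutation equivariance.
#' @return an object of class `lassonet_model`.
#' @export
train_dense <- function(X, Y, split, config = lassonet_config(), init = NULL) {
  stopifnot(inherits(split, "data_split"))
  xy <- as_xy(X, Y, config$task)
  p <- ncol(xy$X); k <- xy$k
  hidden <- config$hidden_sizes %||% min(100L, max(2L, ceiling(p / 3)))
  st <- standardize_fit(xy$X, split$train_idx, config$standardize)
  Z <- apply_standardize(xy$X, st)
  Ztr <- Z[split$train_idx, , drop = FALSE]
  Zva <- Z[split$val_idx, , drop = FALSE]
  Ytr <- if (config$task == "regression") {
    xy$Y[split$train_idx, , drop = FALSE]
  } else xy$Y[split$train_idx]
  Yva <- if (config$task == "regression") {
    xy$Y[split$val_idx, , drop = FALSE]
  } else xy$Y[split$val_idx]

  par <- init %||% ln_init_params(p, k, hidden, config$seed)
  opt <- if (config$optimizer_dense == "adam") {
    opt_adam(config$learning_rate)
  } else {
    opt_sgdm(config$learning_rate, config$momentum)
  }

  best <- list(par = par, val = Inf, epoch = 0L)
  history <- numeric(0)
  with_seed(derive_seed(config$seed, 11L), {
    stall <- 0L
    for (epoch in seq_len(config$epochs_dense)) {
      batches <- make_batches(nrow(Ztr), config$batch_size)
      for (idx in batches) {
        Yb <- if (config$task == "regression") {
          Ytr[idx, , drop = FALSE]
        } else Ytr[idx]
        lg <- ln_loss_grad(par, Ztr[idx, , drop = FALSE], Yb, config$task)
        check_finite_loss(lg$loss, config$learning_rate)
        stp <- opt_step(opt, par, lg$grad)
        opt <- stp$opt; par <- stp$par
      }
      vl <- ln_val_loss(par, Zva, Yva, config$task)
      check_finite_loss(vl, config$learning_rate)
      history <- c(history, vl)
      if (vl < best$val - 1e-12) {
        best <- list(par = par, val = vl, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })

  structure(
    list(theta = best$par$theta, layers = best$par$layers, nu = config$nu,
         lambda = 0, task = config$task, hidden_sizes = hidden,
         center = st$center, scale = st$scale,
         marker_ids = colnames(xy$X) %||% paste0("M", seq_len(p)),
         trait_names = if (config$task == "regression") {
           colnames(xy$Y) %||% paste0("T", seq_len(k))
         } else paste0("class", seq_len(k) - 1L),
         val_loss = best$val, history = history, config = config),
    class = "lassonet_model"
  )
}

#' @export
print.lassonet_model <- function(x, ...) {
  supp <- sum(rowSums(abs(x$theta)) > 0)
  cat(sprintf(
    "<lassonet_model> %s, p = %d, k = %d, hidden = %s, nu = %g, lambda = %g, support = %d\n",
    x$task, nrow(x$theta), ncol(x$theta),
    paste(x$hidden_sizes, collapse = "-"), x$nu, x$lambda, supp))
  invisible(x)
}

#' Network forward pass
#'
#' Evaluates a fitted model on new marker data: for LassoNet the linear skip
#' term plus the feed-forward term; outputs are trait predictions
#' (regression) or class logits (classification).
#'
#' @param model a fitted model object.
#' @param X `n x p` marker matrix (numeric or [genotype_matrix()]).
#' @return `n x k` numeric matrix of predictions or logits.
#' @export
forward <- function(model, X) UseMethod("forward")

#' @export
forward.lassonet_model <- function(model, X) {
  if (inherits(X, "genotype_matrix")) X <- X$values
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != nrow(model$theta)) {
    stop_mtgwp("X has ", ncol(X), " columns but the model expects ",
               nrow(model$theta), class = "mtgwp_precondition_error")
  }
  Z <- apply_standardize(X, list(center = model$center, scale = model$scale))
  ln_forward_raw(list(theta = model$theta, layers = model$layers), Z)
}

#' @export
predict.lassonet_model <- function(object, newdata,
                                   type = c("response", "probs"), ...) {
  type <- match.arg(type)
  out <- forward(object, newdata)
  if (object$task == "classification" && type == "probs") {
    softmax_rows(out)
  } else if (object$task == "classification" && type == "response") {
    max.col(out, ties.method = "first") - 1L
  } else {
    out
  }
}

# Count how many feature rows one proximal application at `lam` would zero.
prox_drop_count <- function(par, lam, lr, nu, convention) {
  res <- prox_rows(par$theta, par$layers[[1L]]$W, lr * lam, nu,
                   convention = convention)
  sum(rowSums(abs(res$theta)) == 0)
}

#' Fit the dense-to-sparse LassoNet regularization path
#'
#' Starting from a well-trained dense model, repeatedly increases the L1
#' penalty `lambda` by `path_multiplier` and, at each value, runs
#' `epochs_per_step` epochs of gradient descent with momentum in which every
#' parameter update is followed by the hierarchical proximal operator
#' [hier_prox()] applied to every feature row. Each step warm-starts from the
#' previous model, so the path moves monotonically from the dense network to
#' an empty support; one path point (penalty, validation loss, support size,
#' skip coefficients) is recorded per `lambda`.
#'
#' @inheritParams train_dense
#' @param dense optional pre-trained dense model from [train_dense()]; fitted
#'   here when missing.
#' @param keep_theta store the skip-coefficient matrix of every path point
#'   (default `TRUE`).
#' @return an object of class `lassonet_path`: `points` (data.frame with
#'   columns `lambda`, `val_metric`, `support`), `theta` (list of skip
#'   matrices), `best_index`, and `best_model` (full model snapshot at the
#'   validation-optimal point).
#' @export
fit_path <- function(X, Y, split, config = lassonet_config(), dense = NULL,
                     keep_theta = TRUE) {
  stopifnot(inherits(split, "data_split"))
  if (is.null(dense)) dense <- train_dense(X, Y, split, config)
  xy <- as_xy(X, Y, config$task)
  p <- ncol(xy$X)
  st <- list(center = dense$center, scale = dense$scale)
  Z <- apply_standardize(xy$X, st)
  Ztr <- Z[split$train_idx, , drop = FALSE]
  Zva <- Z[split$val_idx, , drop = FALSE]
  Ytr <- if (config$task == "regression") {
    xy$Y[split$train_idx, , drop = FALSE]
  } else xy$Y[split$train_idx]
  Yva <- if (config$task == "regression") {
    xy$Y[split$val_idx, , drop = FALSE]
  } else xy$Y[split$val_idx]

  par <- list(theta = dense$theta, layers = dense$layers)
  lr <- config$learning_rate
  nu <- config$nu
  conv <- config$penalty

  lambda <- config$lambda_start
  if (identical(lambda, "auto")) {
    lambda <- (max(rowSums(abs(par$theta))) + max(abs(par$layers[[1L]]$W)) +
                 1e-8) / lr
    while (lambda > 1e-9 &&
           prox_drop_count(par, lambda, lr, nu, conv) > 0.05 * p) {
      lambda <- lambda / 1.5
    }
    # one application dropping <5% still compounds over a step's many
    # proximal iterations; back off so the first recorded point stays dense
    lambda <- lambda / 4
  }
  stopifnot(is.numeric(lambda), lambda > 0)

  active <- rep(TRUE, p)
  points <- list()
  thetas <- list()
  best <- list(metric = Inf, support = Inf, index = 0L, par = NULL,
               lambda = NA_real_)

  with_seed(derive_seed(config$seed, 13L), {
    for (step in seq_len(config$max_steps)) {
      opt <- opt_sgdm(lr, config$momentum)
      prev_theta <- par$theta
      for (epoch in seq_len(config$epochs_per_step)) {
        batches <- make_batches(nrow(Ztr), config$batch_size)
        for (idx in batches) {
          Yb <- if (config$task == "regression") {
            Ytr[idx, , drop = FALSE]
          } else Ytr[idx]
          lg <- ln_loss_grad(par, Ztr[idx, , drop = FALSE], Yb, config$task)
          check_finite_loss(lg$loss, lr)
          stp <- opt_step(opt, par, lg$grad)
          opt <- stp$opt; par <- stp$par
          pr <- prox_rows(par$theta, par$layers[[1L]]$W, lr * lambda, nu,
                          active = active, convention = conv)
          par$theta <- pr$theta
          par$layers[[1L]]$W <- pr$w
        }
        if (!is.null(config$inner_tol)) {
          if (mean(abs(par$theta - prev_theta)) < config$inner_tol) break
          prev_theta <- par$theta
        }
      }
      if (config$freeze_dropped) {
        active <- active & (rowSums(abs(par$theta)) > 0)
      }
      support <- sum(rowSums(abs(par$theta)) > 0)
      vm <- ln_val_loss(par, Zva, Yva, config$task)
      points[[step]] <- data.frame(lambda = lambda, val_metric = vm,
                                   support = support)
      if (keep_theta) thetas[[step]] <- par$theta
      if (vm < best$metric - 1e-15 ||
          (vm <= best$metric && support < best$support)) {
        best <- list(metric = vm, support = support, index = step, par = par,
                     lambda = lambda)
      }
      if (support == 0L) break
      lambda <- lambda * config$path_multiplier
    }
  })

  points <- do.call(rbind, points)
  supp <- points$support
  if (any(diff(supp) > 0)) {
    stop_mtgwp("support size increased along the path (internal invariant)",
               class = "mtgwp_internal_error")
  }
  best_model <- dense
  best_model$theta <- best$par$theta
  best_model$layers <- best$par$layers
  best_model$lambda <- best$lambda
  best_model$val_loss <- best$metric

  structure(
    list(points = points, theta = if (keep_theta) thetas else NULL,
         best_index = best$index, best_model = best_model,
         dense_model = dense, config = config),
    class = "lassonet_path"
  )
}

#' @export
print.lassonet_path <- function(x, ...) {
  cat(sprintf(
    "<lassonet_path> %d points, lambda %.3g..%.3g, best support %d (val metric %.4g)\n",
    nrow(x$points), min(x$points$lambda), max(x$points$lambda),
    x$points$support[x$best_index], x$points$val_metric[x$best_index]))
  invisible(x)
}

#' Select the validation-optimal point of a regularization path
#'
#' Returns the path point with the best (smallest) validation metric; exact
#' ties are broken toward the smaller support.
#'
#' @param path a [fit_path()] result, or any list with a `points` data.frame
#'   holding `lambda`, `val_metric` and `support` columns.
#' @return a list with `index`, `lambda`, `val_metric`, `support` and (when
#'   available on the path object) `model`, the full snapshot at that point.
#' @export
select_model <- function(path) {
  pts <- path$points
  if (is.null(pts) || nrow(pts) == 0L) {
    stop_mtgwp("empty path", class = "mtgwp_precondition_error")
  }
  ord <- order(pts$val_metric, pts$support)
  i <- ord[1L]
  model <- if (!is.null(path$best_index) && !is.null(path$best_model) &&
               i == path$best_index) {
    path$best_model
  } else {
    NULL
  }
  list(index = i, lambda = pts$lambda[i], val_metric = pts$val_metric[i],
       support = pts$support[i], model = model)
}

#' Per-trait selected markers of a LassoNet model
#'
#' Exports, for each trait (or class), the markers whose skip coefficient is
#' non-zero together with the coefficient values — the model's built-in
#' variable selection.
#'
#' @param model a fitted `lassonet_model` (or a path point's skip matrix).
#' @param marker_ids optional marker identifiers (default: the model's).
#' @return an object of class `selection_report`: `per_trait`, a named list
#'   of data.frames (`marker`, `coefficient`), and `counts`, the per-trait
#'   numbers of selected markers.
#' @export
selected_features <- function(model, marker_ids = NULL) {
  theta <- if (inherits(model, "lassonet_model")) model$theta else as.matrix(model)
  ids <- marker_ids %||%
    (if (inherits(model, "lassonet_model")) model$marker_ids else
      paste0("M", seq_len(nrow(theta))))
  traits <- if (inherits(model, "lassonet_model")) model$trait_names else
    paste0("T", seq_len(ncol(theta)))
  per_trait <- lapply(seq_len(ncol(theta)), function(t) {
    nz <- which(abs(theta[, t]) > 0)
    data.frame(marker = ids[nz], coefficient = theta[nz, t],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(per_trait) <- traits
  counts <- vapply(per_trait, nrow, integer(1))
  structure(list(per_trait = per_trait, counts = counts),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> markers selected per trait:\n")
  for (t in names(x$per_trait)) {
    cat(sprintf("  %s: %d\n", t, x$counts[[t]]))
  }
  invisible(x)
}
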