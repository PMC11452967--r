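#' GANDALF training configuration
#'
#' Hyperparameters for the gated adaptive network: a stack of Gated Feature
#' Learning Units (GFLUs), each applying a learnable sparse feature mask to
#' the raw inputs and a GRU-style update/reset gate pair to the running
#' feature representation, followed by a multilayer-perceptron head.
#'
#' @param n_stages number of stacked GFLUs (0 degenerates to the head acting
#'   on the raw standardized inputs).
#' @param dim dimension of the stage-wise feature representation `phi`.
#' @param head_hidden hidden width of the MLP head.
#' @param epochs maximum training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size (`Inf` for full batch).
#' @param patience early-stopping patience on validation loss.
#' @param init_temperature initial t-softmax temperature (learnable,
#'   per stage, kept positive via a log parameterization).
#' @param seed integer seed for initialization and batch order.
#' @param task `"regression"` or `"classification"`.
#' @param standardize center/scale markers with training-partition statistics.
#' @return an object of class `gandalf_config`.
#' @export
gandalf_config <- function(n_stages = 4, dim = 64, head_hidden = 32,
                           epochs = 200, learning_rate = 0.01,
                           batch_size = 64, patience = 10,
                           init_temperature = 1,
                           seed = 1L, task = c("regression", "classification"),
                           standardize = TRUE) {
  task <- match.arg(task)
  if (n_stages < 0 || n_stages != round(n_stages)) {
    stop_mtgwp("n_stages must be a non-negative integer",
               class = "mtgwp_config_error")
  }
  if (init_temperature <= 0) {
    stop_mtgwp("init_temperature must be positive", class = "mtgwp_config_error")
  }
  structure(
    list(n_stages = as.integer(n_stages), dim = as.integer(dim),
         head_hidden = as.integer(head_hidden), epochs = as.integer(epochs),
         learning_rate = learning_rate, batch_size = batch_size,
         patience = as.integer(patience), init_temperature = init_temperature,
         seed = as.integer(seed), task = task, standardize = standardize),
    class = "gandalf_config"
  )
}

#' Temperature-scaled sparse softmax
#'
#' Computes `softmax(logits / t)` and emulates the sparse behaviour of the
#' mask activation by setting entries below `1e-6` times the maximum to
#' exactly zero, then renormalizing to the simplex. The result is a
#' non-negative vector summing to 1; as `t` shrinks with one dominant logit
#' the mask approaches a one-hot vector.
#'
#' @param logits numeric vector of mask logits.
#' @param t temperature, strictly positive.
#' @return numeric mask vector on the simplex.
#' @export
t_softmax <- function(logits, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0) {
    stop_mtgwp("temperature t must be strictly positive",
               class = "mtgwp_config_error")
  }
  u <- logits / t
  u <- u - max(u)
  y <- exp(u)
  y <- y / sum(y)
  y[y < 1e-6 * max(y)] <- 0
  y / sum(y)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameters and forward pass -----------------------------------------

glorot <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

gandalf_init <- function(p, k, config) {
  with_seed(config$seed, {
    d <- config$dim
    stages <- lapply(seq_len(config$n_stages), function(i) {
      list(mask_logits = numeric(p), log_t = log(config$init_temperature),
           Wz = glorot(d + p, d), bz = numeric(d),
           Wr = glorot(d + p, d), br = numeric(d),
           Wo = glorot(d + p, d), bo = numeric(d))
    })
    in_dim <- if (config$n_stages > 0L) d else p
    head <- list(list(W = glorot(in_dim, config$head_hidden),
                      b = numeric(config$head_hidden)),
                 list(W = glorot(config$head_hidden, k), b = numeric(k)))
    proj <- if (config$n_stages > 0L) {
      list(W0 = glorot(p, d), b0 = numeric(d))
    } else {
      list()
    }
    c(list(stages = stages, head = head), proj)
  })
}

stage_mask <- function(stage) t_softmax(stage$mask_logits, exp(stage$log_t))

# One GFLU stage on a batch: Phi (n x d), X (n x p, standardized), returns
# the updated representation and (optionally) the cache for backprop.
gflu_forward <- function(Phi, X, stage, keep_cache = FALSE) {
  M <- stage_mask(stage)
  Xn <- sweep(X, 2L, M, "*")
  Cz <- cbind(Phi, Xn)
  z <- sigmoid(Cz %*% stage$Wz + rep(stage$bz, each = nrow(X)))
  r <- sigmoid(Cz %*% stage$Wr + rep(stage$br, each = nrow(X)))
  Co <- cbind(r * Phi, Xn)
  phihat <- tanh(Co %*% stage$Wo + rep(stage$bo, each = nrow(X)))
  Phi_new <- (1 - z) * Phi + z * phihat
  if (keep_cache) {
    list(Phi = Phi_new,
         cache = list(M = M, Xn = Xn, Cz = Cz, Co = Co, z = z, r = r,
                      phihat = phihat, Phi_prev = Phi))
  } else {
    Phi_new
  }
}

#' One gated feature learning unit step
#'
#' Applies a single GFLU stage to a previous representation and a raw input
#' row: the stage mask selects features (`X_n = M_n * x`), the update gate
#' `z = sigmoid(Wz [phi; X_n])` decides how much of the representation to
#' rewrite, the reset gate `r = sigmoid(Wr [phi; X_n])` how much of the
#' previous representation feeds the candidate
#' `phihat = tanh(Wo [r * phi; X_n])`, and the new representation is the
#' GRU-style blend `(1 - z) * phi + z * phihat`.
#'
#' @param phi_prev numeric d-vector, the previous stage representation.
#' @param X_row numeric p-vector of input features.
#' @param stage stage parameter list with elements `mask_logits`, `log_t`,
#'   `Wz`, `bz`, `Wr`, `br`, `Wo`, `bo` (as stored in a fitted
#'   `gandalf_model`).
#' @return numeric d-vector, the updated representation.
#' @export
gflu_step <- function(phi_prev, X_row, stage) {
  d <- length(phi_prev)
  if (nrow(stage$Wz) != d + length(X_row)) {
    stop_mtgwp("stage weight shapes are inconsistent with phi_prev/X_row",
               class = "mtgwp_precondition_error")
  }
  drop(gflu_forward(matrix(phi_prev, 1L), matrix(X_row, 1L), stage))
}

gandalf_forward_raw <- function(par, X, keep_cache = FALSE) {
  n <- nrow(X)
  caches <- list()
  if (length(par$stages) > 0L) {
    M1 <- stage_mask(par$stages[[1L]])
    X1 <- sweep(X, 2L, M1, "*")
    Phi <- X1 %*% par$W0 + rep(par$b0, each = n)
    proj_cache <- list(X1 = X1)
    for (s in seq_along(par$stages)) {
      fw <- gflu_forward(Phi, X, par$stages[[s]], keep_cache = keep_cache)
      if (keep_cache) {
        caches[[s]] <- fw$cache
        Phi <- fw$Phi
      } else {
        Phi <- fw
      }
    }
    A <- Phi
  } else {
    proj_cache <- NULL
    A <- X
  }
  pre1 <- A %*% par$head[[1L]]$W + rep(par$head[[1L]]$b, each = n)
  H <- relu(pre1)
  out <- H %*% par$head[[2L]]$W + rep(par$head[[2L]]$b, each = n)
  if (keep_cache) {
    list(out = out, head_in = A, pre1 = pre1, H = H, caches = caches,
         proj = proj_cache)
  } else {
    out
  }
}

# Softmax jacobian-vector product used by the mask backward pass (the hard
# zero clipping of t_softmax is treated as identity, i.e. straight-through).
softmax_backward <- function(y, dy) y * (dy - sum(dy * y))

gandalf_loss_grad <- function(par, X, Y, task) {
  fw <- gandalf_forward_raw(par, X, keep_cache = TRUE)
  ld <- loss_and_dout(fw$out, Y, task)
  n <- nrow(X)
  d2 <- ld$dout
  ghead2 <- list(W = crossprod(fw$H, d2), b = colSums(d2))
  dH <- d2 %*% t(par$head[[2L]]$W)
  d1 <- dH * (fw$pre1 > 0)
  ghead1 <- list(W = crossprod(fw$head_in, d1), b = colSums(d1))
  dA <- d1 %*% t(par$head[[1L]]$W)

  grad <- list(stages = vector("list", length(par$stages)),
               head = list(ghead1, ghead2))
  if (length(par$stages) == 0L) {
    return(list(loss = ld$loss, grad = grad))
  }

  dPhi <- dA
  dM_list <- vector("list", length(par$stages))
  for (s in rev(seq_along(par$stages))) {
    st <- par$stages[[s]]
    cc <- fw$caches[[s]]
    dz <- dPhi * (cc$phihat - cc$Phi_prev)
    dphihat <- dPhi * cc$z
    dPhi_prev <- dPhi * (1 - cc$z)

    dAo <- dphihat * (1 - cc$phihat^2)
    gWo <- crossprod(cc$Co, dAo)
    gbo <- colSums(dAo)
    dCo <- dAo %*% t(st$Wo)
    dvec <- ncol(cc$Phi_prev)
    drPhi <- dCo[, seq_len(dvec), drop = FALSE]
    dXn <- dCo[, -seq_len(dvec), drop = FALSE]
    dr <- drPhi * cc$Phi_prev
    dPhi_prev <- dPhi_prev + drPhi * cc$r

    dAr <- dr * cc$r * (1 - cc$r)
    gWr <- crossprod(cc$Cz, dAr)
    gbr <- colSums(dAr)
    dCr <- dAr %*% t(st$Wr)
    dPhi_prev <- dPhi_prev + dCr[, seq_len(dvec), drop = FALSE]
    dXn <- dXn + dCr[, -seq_len(dvec), drop = FALSE]

    dAz <- dz * cc$z * (1 - cc$z)
    gWz <- crossprod(cc$Cz, dAz)
    gbz <- colSums(dAz)
    dCz <- dAz %*% t(st$Wz)
    dPhi_prev <- dPhi_prev + dCz[, seq_len(dvec), drop = FALSE]
    dXn <- dXn + dCz[, -seq_len(dvec), drop = FALSE]

    grad$stages[[s]] <- list(mask_logits = NULL, log_t = NULL,
                             Wz = gWz, bz = gbz, Wr = gWr, br = gbr,
                             Wo = gWo, bo = gbo)
    dM_list[[s]] <- colSums(X * dXn)
    dPhi <- dPhi_prev
  }

  # Projection of the stage-1 masked input into phi_0.
  gW0 <- crossprod(fw$proj$X1, dPhi)
  gb0 <- colSums(dPhi)
  dX1 <- dPhi %*% t(par$W0)
  dM_list[[1L]] <- dM_list[[1L]] + colSums(X * dX1)

  for (s in seq_along(par$stages)) {
    st <- par$stages[[s]]
    t_val <- exp(st$log_t)
    u <- st$mask_logits / t_val
    u <- u - max(u)
    y <- exp(u); y <- y / sum(y)
    du <- softmax_backward(y, dM_list[[s]])
    grad$stages[[s]]$mask_logits <- du / t_val
    grad$stages[[s]]$log_t <- -sum(du * st$mask_logits / t_val)
  }
  grad$W0 <- gW0
  grad$b0 <- gb0
  list(loss = ld$loss, grad = grad)
}

# ---- fitting -------------------------------------------------------------

#' Fit a GANDALF model
#'
#' End-to-end gradient training (Adam) of the stage masks, temperatures,
#' gates, representation projection and MLP head on the multivariate loss,
#' with early stopping on the validation partition.
#'
#' @inheritParams train_dense
#' @param config a [gandalf_config()].
#' @return an object of class `gandalf_model`.
#' @export
fit_gandalf <- function(X, Y, split, config = gandalf_config()) {
  stopifnot(inherits(split, "data_split"))
  xy <- as_xy(X, Y, config$task)
  p <- ncol(xy$X); k <- xy$k
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

  par <- gandalf_init(p, k, config)
  opt <- opt_adam(config$learning_rate)
  best <- list(par = par, val = Inf)
  history <- numeric(0)
  with_seed(derive_seed(config$seed, 17L), {
    stall <- 0L
    for (epoch in seq_len(config$epochs)) {
      batches <- make_batches(nrow(Ztr), config$batch_size)
      for (idx in batches) {
        Yb <- if (config$task == "regression") {
          Ytr[idx, , drop = FALSE]
        } else Ytr[idx]
        lg <- gandalf_loss_grad(par, Ztr[idx, , drop = FALSE], Yb, config$task)
        check_finite_loss(lg$loss, config$learning_rate)
        stp <- opt_step(opt, par, lg$grad)
        opt <- stp$opt; par <- stp$par
      }
      vl <- loss_and_dout(gandalf_forward_raw(par, Zva), Yva, config$task)$loss
      check_finite_loss(vl, config$learning_rate)
      history <- c(history, vl)
      if (vl < best$val - 1e-12) {
        best <- list(par = par, val = vl)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })

  structure(
    list(par = best$par, task = config$task, center = st$center,
         scale = st$scale,
         marker_ids = colnames(xy$X) %||% paste0("M", seq_len(p)),
         k = k, val_loss = best$val, history = history, config = config),
    class = "gandalf_model"
  )
}

#' @export
forward.gandalf_model <- function(model, X) {
  if (inherits(X, "genotype_matrix")) X <- X$values
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  Z <- apply_standardize(X, list(center = model$center, scale = model$scale))
  gandalf_forward_raw(model$par, Z)
}

#' @export
predict.gandalf_model <- function(object, newdata,
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

#' @export
print.gandalf_model <- function(x, ...) {
  cat(sprintf("<gandalf_model> %s, p = %d, %d stages, dim = %d\n",
              x$task, length(x$marker_ids), length(x$par$stages),
              x$config$dim))
  invisible(x)
}

#' Per-stage feature masks of a fitted GANDALF model
#'
#' @param model a fitted `gandalf_model`.
#' @return a `p x n_stages` matrix of mask weights (columns on the simplex),
#'   with marker ids as row names; interpretable as per-stage soft feature
#'   selection.
#' @export
gandalf_masks <- function(model) {
  stopifnot(inherits(model, "gandalf_model"))
  if (length(model$par$stages) == 0L) {
    return(matrix(numeric(0), nrow = length(model$marker_ids), ncol = 0,
                  dimnames = list(model$marker_ids, NULL)))
  }
  m <- vapply(model$par$stages, stage_mask, numeric(length(model$marker_ids)))
  rownames(m) <- model$marker_ids
  colnames(m) <- paste0("stage", seq_len(ncol(m)))
  m
}
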