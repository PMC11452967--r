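# Minimal "parameter tree" helpers and first-order optimizers used by the
# hand-written network trainers (LassoNet, GANDALF, MLP baseline). Parameters
# are nested lists whose leaves are numeric vectors/matrices; gradients share
# the same shape.

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_map3 <- function(f, a, b, c) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map3(f, a[[i]], b[[i]], c[[i]])
    out
  } else {
    f(a, b, c)
  }
}

tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

# Stochastic gradient descent with classical momentum.
opt_sgdm <- function(lr, momentum = 0.9) {
  structure(list(lr = lr, momentum = momentum, v = NULL), class = "opt_sgdm")
}

# Adaptive-moment estimation (used for the dense warm start).
opt_adam <- function(lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 m = NULL, v = NULL, t = 0L), class = "opt_adam")
}

opt_step <- function(opt, par, grad) UseMethod("opt_step")

#' @export
opt_step.opt_sgdm <- function(opt, par, grad) {
  if (is.null(opt$v)) opt$v <- tree_zeros_like(par)
  opt$v <- tree_map2(function(v, g) opt$momentum * v + g, opt$v, grad)
  par <- tree_map2(function(p, v) p - opt$lr * v, par, opt$v)
  list(opt = opt, par = par)
}

#' @export
opt_step.opt_adam <- function(opt, par, grad) {
  if (is.null(opt$m)) {
    opt$m <- tree_zeros_like(par)
    opt$v <- tree_zeros_like(par)
  }
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(function(m, g) opt$beta1 * m + (1 - opt$beta1) * g,
                     opt$m, grad)
  opt$v <- tree_map2(function(v, g) opt$beta2 * v + (1 - opt$beta2) * g^2,
                     opt$v, grad)
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  par <- tree_map3(function(p, m, v) {
    p - opt$lr * (m / c1) / (sqrt(v / c2) + opt$eps)
  }, par, opt$m, opt$v)
  list(opt = opt, par = par)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

# Multivariate training losses and their gradients w.r.t. the network output.
# Regression: mean squared error over all n*k residuals. Classification:
# softmax cross-entropy over K logits, mean over samples.
loss_and_dout <- function(out, Y, task) {
  n <- nrow(out)
  if (task == "regression") {
    R <- out - Y
    list(loss = sum(R * R) / (n * ncol(out)),
         dout = 2 * R / (n * ncol(out)))
  } else {
    P <- softmax_rows(out)
    idx <- cbind(seq_len(n), Y + 1L)
    eps <- 1e-12
    O <- matrix(0, n, ncol(out))
    O[idx] <- 1
    list(loss = -mean(log(P[idx] + eps)), dout = (P - O) / n)
  }
}
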