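test_that("hier_prox handles the identity, zero and frozen-fixture cases", {
  # already-feasible input with no penalty passes through unchanged
  b <- c(0.4, -0.2); v <- c(0.3, -0.1, 0.2)
  res <- hier_prox(b, v, 0, nu = 1)
  expect_equal(res$theta, b, tolerance = 1e-12)
  expect_equal(res$w, v, tolerance = 1e-12)

  res0 <- hier_prox(c(0, 0), c(0, 0, 0), 0.5, 2)
  expect_identical(res0$theta, c(0, 0))
  expect_identical(res0$w, c(0, 0, 0))

  # k = 1 fixture recorded from the brute-force oracle before the build:
  # b = 0.5, v = (0.8, -0.2), lambda = 0.1, nu = 1 -> theta = 0.6,
  # w = (0.6, -0.2): raising theta past its soft-threshold value relaxes
  # the clamp on the large hidden weight.
  fx <- hier_prox(0.5, c(0.8, -0.2), 0.1, 1)
  expect_equal(fx$theta, 0.6, tolerance = 1e-6)
  expect_equal(fx$w, c(0.6, -0.2), tolerance = 1e-6)
  orc <- prox_oracle(0.5, c(0.8, -0.2), 0.1, 1)
  expect_equal(fx$theta, orc$theta, tolerance = 1e-6)
  expect_equal(fx$w, orc$w, tolerance = 1e-6)
})

test_that("hier_prox limits: nu = 0 soft-thresholds, nu = Inf is unconstrained", {
  b <- c(0.7, -0.05); v <- c(1.5, -0.4)
  r0 <- hier_prox(b, v, 0.1, 0)
  expect_equal(r0$theta, c(0.6, 0), tolerance = 1e-12)
  expect_identical(r0$w, c(0, 0))
  rI <- hier_prox(b, v, 0.1, Inf)
  expect_equal(rI$theta, c(0.6, 0), tolerance = 1e-12)
  expect_identical(rI$w, v)
})

test_that("hier_prox matches the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:300) {
    k <- sample(1:3, 1); h <- sample(1:8, 1)
    b <- rnorm(k); v <- rnorm(h)
    lam <- exp(runif(1, log(1e-3), log(2)))
    nu <- exp(runif(1, log(1e-2), log(10)))
    res <- hier_prox(b, v, lam, nu)
    orc <- prox_oracle(b, v, lam, nu)
    expect_equal(res$theta, orc$theta, tolerance = 1e-6)
    expect_equal(res$w, orc$w, tolerance = 1e-6)
    # zero skip row forces a zero hidden row
    if (all(res$theta == 0)) expect_true(all(res$w == 0))
    # feasibility is exact
    if (is.finite(nu)) {
      expect_lte(max(abs(res$w)), nu * max(abs(res$theta)) + 1e-12)
    }
  }
})

test_that("grouped selection convention reduces to elementwise at k = 1", {
  set.seed(7)
  for (i in 1:20) {
    b <- rnorm(1); v <- rnorm(5); lam <- runif(1, 0, 1); nu <- runif(1, 0.1, 3)
    e <- hier_prox(b, v, lam, nu, convention = "elementwise")
    g <- hier_prox(b, v, lam, nu, convention = "grouped")
    expect_equal(e$theta, g$theta, tolerance = 1e-10)
    expect_equal(e$w, g$w, tolerance = 1e-10)
  }
})

test_that("forward reduces to the linear predictor when the network is zeroed", {
  p <- 6; k <- 2
  par <- mtgwp:::ln_init_params(p, k, 4, seed = 1)
  par$layers <- lapply(par$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  par$theta <- matrix(rnorm(p * k), p, k)
  X <- matrix(rnorm(30 * p), 30, p)
  expect_equal(mtgwp:::ln_forward_raw(par, X), X %*% par$theta,
               tolerance = 1e-12)

  # theta = 0 under the hierarchy constraint zeroes the first layer:
  # output is then constant in X (biases only)
  par2 <- mtgwp:::ln_init_params(p, k, 4, seed = 2)
  pr <- mtgwp:::prox_rows(matrix(0, p, k), par2$layers[[1]]$W, 0.1, nu = 0)
  par2$theta <- pr$theta
  par2$layers[[1]]$W <- pr$w
  out <- mtgwp:::ln_forward_raw(par2, X)
  expect_equal(max(apply(out, 2, sd)), 0, tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(3)
  p <- 7; k <- 2; n <- 11
  par <- mtgwp:::ln_init_params(p, k, c(5, 4), seed = 3)
  par$theta <- matrix(rnorm(p * k), p, k) * 0.3
  Z <- matrix(rnorm(n * p), n, p)
  for (task in c("regression", "classification")) {
    Y <- if (task == "regression") matrix(rnorm(n * k), n, k) else
      sample(0:(k - 1), n, replace = TRUE)
    lg <- mtgwp:::ln_loss_grad(par, Z, Y, task)
    fd_at <- function(mod) {
      eps <- 1e-6
      (mtgwp:::ln_loss_grad(mod(par, eps), Z, Y, task)$loss -
         mtgwp:::ln_loss_grad(mod(par, -eps), Z, Y, task)$loss) / (2 * eps)
    }
    checks <- list(
      list(g = lg$grad$theta[3, 2],
           m = function(q, e) { q$theta[3, 2] <- q$theta[3, 2] + e; q }),
      list(g = lg$grad$layers[[1]]$W[2, 3],
           m = function(q, e) {
             q$layers[[1]]$W[2, 3] <- q$layers[[1]]$W[2, 3] + e; q
           }),
      list(g = lg$grad$layers[[2]]$b[1],
           m = function(q, e) {
             q$layers[[2]]$b[1] <- q$layers[[2]]$b[1] + e; q
           }),
      list(g = lg$grad$layers[[3]]$W[4, 1],
           m = function(q, e) {
             q$layers[[3]]$W[4, 1] <- q$layers[[3]]$W[4, 1] + e; q
           })
    )
    for (ch in checks) {
      fd <- fd_at(ch$m)
      expect_equal(ch$g, fd, tolerance = 1e-5)
    }
  }
})

test_that("dense training fits a realizable linear target and is deterministic", {
  set.seed(5)
  n <- 120; p <- 15; k <- 2
  X <- matrix(rnorm(n * p), n, p)
  theta_star <- matrix(rnorm(p * k), p, k)
  Y <- X %*% theta_star
  sp <- split_data(n, seed = 2)
  cfg <- lassonet_config(hidden_sizes = 20, epochs_dense = 300,
                         learning_rate = 0.02, patience = 50, seed = 9,
                         batch_size = 32, task = "regression")
  m <- train_dense(X, Y, sp, cfg)
  r <- pearson_r_mean(Y[sp$val_idx, ], predict(m, X[sp$val_idx, ]))
  expect_gt(r, 0.95)

  m2 <- train_dense(X, Y, sp, cfg)
  expect_identical(m$theta, m2$theta)
  expect_identical(m$layers, m2$layers)

  bad <- lassonet_config(hidden_sizes = 20, epochs_dense = 30,
                         learning_rate = 1e10, optimizer_dense = "sgdm",
                         seed = 1, task = "regression")
  expect_error(train_dense(X, Y, sp, bad), "learning rate",
               class = "mtgwp_divergence_error")
})

test_that("training is equivariant under marker permutation", {
  set.seed(6)
  n <- 60; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(X %*% rnorm(p) + 0.1 * rnorm(n), ncol = 1)
  sp <- split_data(n, seed = 1)
  cfg <- lassonet_config(hidden_sizes = 6, epochs_dense = 40,
                         learning_rate = 0.02, patience = 40, seed = 4,
                         batch_size = Inf, standardize = FALSE,
                         task = "regression")
  init <- mtgwp:::ln_init_params(p, 1, 6, seed = 4)
  perm <- sample(p)
  init_p <- init
  init_p$theta <- init$theta[perm, , drop = FALSE]
  init_p$layers[[1]]$W <- init$layers[[1]]$W[perm, , drop = FALSE]
  m1 <- train_dense(X, Y, sp, cfg, init = init)
  m2 <- train_dense(X[, perm], Y, sp, cfg, init = init_p)
  expect_equal(m2$theta, m1$theta[perm, , drop = FALSE], tolerance = 1e-8)
})

test_that("a huge initial lambda empties the support immediately", {
  dat <- toy_regression(n = 60, p = 20, k = 1, seed = 3)
  cfg <- lassonet_config(hidden_sizes = 5, nu = 5, lambda_start = 1e6,
                         epochs_dense = 30, epochs_per_step = 2,
                         learning_rate = 0.01, seed = 1, task = "regression")
  path <- fit_path(dat$G, dat$traits, dat$split, cfg)
  expect_identical(nrow(path$points), 1L)
  expect_identical(path$points$support, 0L)
  expect_true(all(path$theta[[1]] == 0))
})

test_that("select_model picks the argmin and breaks ties toward smaller support", {
  one <- list(points = data.frame(lambda = 1, val_metric = 0.4, support = 3L))
  expect_identical(select_model(one)$index, 1L)

  multi <- list(points = data.frame(lambda = 1:3,
                                    val_metric = c(0.5, 0.3, 0.4),
                                    support = c(30L, 20L, 10L)))
  expect_identical(select_model(multi)$index, 2L)

  tie <- list(points = data.frame(lambda = 1:2, val_metric = c(0.3, 0.3),
                                  support = c(50L, 10L)))
  expect_identical(select_model(tie)$support, 10L)

  expect_error(select_model(list(points = NULL)),
               class = "mtgwp_precondition_error")
})

test_that("selected_features reports per-trait nonzero skip coefficients", {
  th <- matrix(0, 5, 2)
  rep0 <- selected_features(th)
  expect_identical(unname(rep0$counts), c(0L, 0L))

  th[2, 1] <- 1.5; th[4, 2] <- -0.3
  rep1 <- selected_features(th, marker_ids = paste0("snp", 1:5))
  expect_identical(unname(rep1$counts), c(1L, 1L))
  expect_identical(rep1$per_trait[[1]]$marker, "snp2")
  expect_identical(rep1$per_trait[[2]]$coefficient, -0.3)
})

test_that("path keeps the hierarchy constraint and support monotone", {
  dat <- toy_regression(n = 100, p = 40, k = 2, seed = 8)
  cfg <- lassonet_config(hidden_sizes = 10, nu = 3, path_multiplier = 1.3,
                         epochs_dense = 60, epochs_per_step = 5,
                         learning_rate = 0.01, seed = 2, task = "regression")
  path <- fit_path(dat$G, dat$traits, dat$split, cfg)
  expect_true(all(diff(path$points$support) <= 0))
  expect_identical(path$points$support[nrow(path$points)], 0L)

  best <- select_model(path)
  th <- best$model$theta
  W1 <- best$model$layers[[1]]$W
  sel <- apply(abs(th), 1, max)
  expect_true(all(apply(abs(W1), 1, max) <= cfg$nu * sel + 1e-10))
  zero_rows <- rowSums(abs(th)) == 0
  expect_true(all(W1[zero_rows, ] == 0))
})
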