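test_that("t_softmax is a simplex mapping with the documented limits", {
  expect_equal(t_softmax(rep(2, 5), 1), rep(0.2, 5), tolerance = 1e-12)

  m <- t_softmax(c(5, 0, 0), 0.01)  # dominant logit, small temperature
  expect_equal(m, c(1, 0, 0), tolerance = 1e-6)

  # closed-form exp-normalize on (2, 1, 0) at t = 1
  e <- exp(c(2, 1, 0))
  expect_equal(t_softmax(c(2, 1, 0), 1), e / sum(e), tolerance = 1e-9)

  expect_error(t_softmax(c(1, 2), 0), class = "mtgwp_config_error")
  expect_error(t_softmax(c(1, 2), -1), class = "mtgwp_config_error")

  set.seed(2)
  for (i in 1:50) {
    m <- t_softmax(rnorm(20, sd = 5), exp(runif(1, -2, 2)))
    expect_true(all(m >= 0))
    expect_equal(sum(m), 1, tolerance = 1e-9)
  }
})

test_that("gflu_step honours the gate limits and matches the transliteration oracle", {
  set.seed(4)
  p <- 6; d <- 3
  stage <- list(mask_logits = rnorm(p), log_t = 0.2,
                Wz = matrix(rnorm((d + p) * d), d + p, d), bz = rnorm(d),
                Wr = matrix(rnorm((d + p) * d), d + p, d), br = rnorm(d),
                Wo = matrix(rnorm((d + p) * d), d + p, d), bo = rnorm(d))
  phi <- rnorm(d); x <- rnorm(p)

  # update gate forced shut: representation unchanged
  shut <- stage; shut$bz <- rep(-100, d); shut$Wz <- shut$Wz * 0
  expect_equal(gflu_step(phi, x, shut), phi, tolerance = 1e-12)

  # update gate forced open: representation equals the candidate
  open <- stage; open$bz <- rep(100, d); open$Wz <- open$Wz * 0
  M <- t_softmax(open$mask_logits, exp(open$log_t))
  xn <- M * x
  r <- mtgwp:::sigmoid(drop(c(phi, xn) %*% open$Wr) + open$br)
  cand <- tanh(drop(c(r * phi, xn) %*% open$Wo) + open$bo)
  expect_equal(gflu_step(phi, x, open), cand, tolerance = 1e-12)

  for (i in 1:20) {
    phi_i <- rnorm(d); x_i <- rnorm(p)
    expect_equal(gflu_step(phi_i, x_i, stage), gflu_oracle(phi_i, x_i, stage),
                 tolerance = 1e-9)
  }
})

test_that("gate outputs stay strictly inside (0, 1)", {
  set.seed(9)
  p <- 5; d <- 4
  cfg <- gandalf_config(n_stages = 2, dim = d, head_hidden = 3, seed = 1,
                        task = "regression")
  par <- mtgwp:::gandalf_init(p, 1, cfg)
  X <- matrix(rnorm(20 * p), 20, p)
  fw <- mtgwp:::gflu_forward(matrix(0, 20, d), X, par$stages[[1]],
                             keep_cache = TRUE)
  expect_true(all(fw$cache$z > 0 & fw$cache$z < 1))
  expect_true(all(fw$cache$r > 0 & fw$cache$r < 1))
})

test_that("gandalf gradients match finite differences", {
  set.seed(11)
  p <- 6; k <- 2; n <- 9
  cfg <- gandalf_config(n_stages = 2, dim = 3, head_hidden = 4, seed = 5,
                        task = "regression")
  par <- mtgwp:::gandalf_init(p, k, cfg)
  # move mask logits off the symmetric zero initialization
  par$stages[[1]]$mask_logits <- rnorm(p, sd = 0.5)
  par$stages[[2]]$mask_logits <- rnorm(p, sd = 0.5)
  Z <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * k), n, k)
  lg <- mtgwp:::gandalf_loss_grad(par, Z, Y, "regression")
  fd_check <- function(get, set, gval) {
    eps <- 1e-6
    q1 <- set(par, get(par) + eps); q2 <- set(par, get(par) - eps)
    fd <- (mtgwp:::gandalf_loss_grad(q1, Z, Y, "regression")$loss -
             mtgwp:::gandalf_loss_grad(q2, Z, Y, "regression")$loss) / (2 * eps)
    expect_equal(gval, fd, tolerance = 1e-4)
  }
  fd_check(function(g) g$stages[[1]]$mask_logits[2],
           function(g, v) { g$stages[[1]]$mask_logits[2] <- v; g },
           lg$grad$stages[[1]]$mask_logits[2])
  fd_check(function(g) g$stages[[2]]$log_t,
           function(g, v) { g$stages[[2]]$log_t <- v; g },
           lg$grad$stages[[2]]$log_t)
  fd_check(function(g) g$stages[[1]]$Wz[8, 1],
           function(g, v) { g$stages[[1]]$Wz[8, 1] <- v; g },
           lg$grad$stages[[1]]$Wz[8, 1])
  fd_check(function(g) g$stages[[2]]$Wo[2, 3],
           function(g, v) { g$stages[[2]]$Wo[2, 3] <- v; g },
           lg$grad$stages[[2]]$Wo[2, 3])
  fd_check(function(g) g$W0[4, 1],
           function(g, v) { g$W0[4, 1] <- v; g },
           lg$grad$W0[4, 1])
})

test_that("gandalf fits a realizable linear target and is deterministic", {
  set.seed(13)
  n <- 150; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(X %*% rnorm(p), ncol = 1)
  sp <- split_data(n, seed = 3)
  cfg <- gandalf_config(n_stages = 1, dim = 16, head_hidden = 16,
                        epochs = 250, learning_rate = 0.02, patience = 40,
                        batch_size = 32, seed = 7, task = "regression")
  m <- fit_gandalf(X, Y, sp, cfg)
  r <- pearson_r_mean(Y[sp$val_idx, , drop = FALSE],
                      predict(m, X[sp$val_idx, ]))
  expect_gt(r, 0.9)

  m2 <- fit_gandalf(X, Y, sp, cfg)
  expect_identical(m$val_loss, m2$val_loss)

  masks <- gandalf_masks(m)
  expect_identical(dim(masks), as.integer(c(p, 1)))
  expect_true(all(masks >= 0))
  expect_equal(colSums(masks), c(stage1 = 1), tolerance = 1e-9)
})

test_that("zero stages degenerate to the MLP head on raw inputs", {
  set.seed(15)
  n <- 80; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(X %*% rnorm(p), ncol = 1)
  sp <- split_data(n, seed = 1)
  cfg <- gandalf_config(n_stages = 0, head_hidden = 16, epochs = 200,
                        learning_rate = 0.02, patience = 30, seed = 2,
                        task = "regression")
  m <- fit_gandalf(X, Y, sp, cfg)
  expect_identical(length(m$par$stages), 0L)
  r <- pearson_r_mean(Y[sp$val_idx, , drop = FALSE],
                      predict(m, X[sp$val_idx, ]))
  expect_gt(r, 0.8)
})
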