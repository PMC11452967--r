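# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: the proximal oracle scans a dense grid over the
# selection magnitude with closed-form scalar sub-solutions and a local
# numeric polish; the AUC oracle is the Mann-Whitney rank-sum formula.

# Brute-force constrained minimizer of the hierarchical proximal problem.
prox_oracle <- function(b, v, lam, nu) {
  phi <- function(M) {
    s <- pmax(abs(b) - lam, 0)
    m0 <- max(s)
    mag <- pmin(s, M)
    cost <- sum(0.5 * (mag - abs(b))^2 + lam * mag)
    if (M > m0) {
      ts <- which.max(abs(b))
      cost <- cost - (0.5 * (s[ts] - abs(b[ts]))^2 + lam * s[ts]) +
        0.5 * (M - abs(b[ts]))^2 + lam * M
    }
    cost + 0.5 * sum(pmax(abs(v) - nu * M, 0)^2)
  }
  if (!is.finite(nu)) {
    s <- pmax(abs(b) - lam, 0)
    return(list(theta = sign(b) * s, w = v))
  }
  if (nu <= 0) {
    s <- pmax(abs(b) - lam, 0)
    return(list(theta = sign(b) * s, w = rep(0, length(v))))
  }
  Mmax <- max(abs(b)) + lam + max(abs(v), 0) / max(nu, 1e-8) + 1
  grid <- seq(0, Mmax, length.out = 2001)
  vals <- vapply(grid, phi, 0)
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  op <- optimize(phi, c(lo, hi), tol = 1e-14)
  M <- if (op$objective < vals[i]) op$minimum else grid[i]
  s <- pmax(abs(b) - lam, 0); m0 <- max(s)
  th <- sign(b) * pmin(s, M)
  if (M > m0) {
    ts <- which.max(abs(b))
    th[ts] <- sign(b[ts]) * M
  }
  list(theta = th, w = pmin(pmax(v, -nu * M), nu * M))
}

# Mann-Whitney rank-sum AUC with midrank tie handling.
auc_ranksum <- function(response, predictor) {
  r <- rank(predictor)
  n1 <- sum(response == 1)
  n0 <- sum(response == 0)
  (sum(r[response == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Straight-line re-implementation of one GFLU stage with explicit loops,
# mirroring the update/reset-gate equations term by term.
gflu_oracle <- function(phi_prev, x, stage) {
  t_val <- exp(stage$log_t)
  u <- stage$mask_logits / t_val
  e <- exp(u - max(u))
  m <- e / sum(e)
  m[m < 1e-6 * max(m)] <- 0
  m <- m / sum(m)
  xn <- m * x
  d <- length(phi_prev)
  cz <- c(phi_prev, xn)
  z <- numeric(d); r <- numeric(d)
  for (j in seq_len(d)) {
    z[j] <- 1 / (1 + exp(-(sum(cz * stage$Wz[, j]) + stage$bz[j])))
    r[j] <- 1 / (1 + exp(-(sum(cz * stage$Wr[, j]) + stage$br[j])))
  }
  co <- c(r * phi_prev, xn)
  phihat <- numeric(d)
  for (j in seq_len(d)) {
    phihat[j] <- tanh(sum(co * stage$Wo[, j]) + stage$bo[j])
  }
  (1 - z) * phi_prev + z * phihat
}

# Small simulated regression problem reused by several tests.
toy_regression <- function(n = 80, p = 30, k = 2, seed = 1) {
  cfg <- sim_config(n_samples = n, n_markers = p, n_traits = k,
                    n_qtl_shared = 5, heritability = 0.8, ld_rho = 0,
                    ld_block_size = 5, seed = seed)
  G <- simulate_genotypes(cfg)
  st <- simulate_traits(G, cfg)
  list(G = G, traits = st$traits, truth = st$truth,
       split = split_data(n, seed = seed), cfg = cfg)
}
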