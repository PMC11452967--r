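test_that("simulated genotypes honour coding, MAF range and determinism", {
  cfg <- sim_config(n_samples = 3000, n_markers = 100, n_traits = 1,
                    maf_range = c(0.3, 0.3), ld_rho = 0, ld_block_size = 5,
                    seed = 2)
  G <- simulate_genotypes(cfg)
  expect_s3_class(G, "genotype_matrix")
  expect_true(all(G$values %in% 0:2))
  # binomial expectation: mean dosage per marker = 2 * 0.3
  expect_equal(mean(colMeans(G$values)), 0.6, tolerance = 0.02)
  expect_true(all(abs(colMeans(G$values) / 2 - 0.3) < 0.05))

  G2 <- simulate_genotypes(cfg)
  expect_identical(G$values, G2$values)
  G3 <- simulate_genotypes(sim_config(n_samples = 3000, n_markers = 100,
                                      n_traits = 1, maf_range = c(0.3, 0.3),
                                      ld_rho = 0, ld_block_size = 5, seed = 3))
  expect_false(identical(G$values, G3$values))

  dom <- simulate_genotypes(sim_config(n_samples = 2000, n_markers = 50,
                                       coding = "dominant_01",
                                       maf_range = c(0.2, 0.4), ld_rho = 0,
                                       seed = 4))
  expect_true(all(dom$values %in% 0:1))
  expect_true(all(colMeans(dom$values) > 0.1 & colMeans(dom$values) < 0.5))
})

test_that("linkage disequilibrium is present within blocks and absent across", {
  cfg0 <- sim_config(n_samples = 2000, n_markers = 60, ld_rho = 0,
                     ld_block_size = 10, maf_range = c(0.2, 0.5), seed = 5)
  C0 <- cor(simulate_genotypes(cfg0)$values)
  off <- abs(C0[upper.tri(C0)])
  expect_lt(mean(off), 0.03)  # independence case

  cfg6 <- sim_config(n_samples = 2000, n_markers = 60, ld_rho = 0.6,
                     ld_block_size = 10, maf_range = c(0.2, 0.5), seed = 5)
  G6 <- simulate_genotypes(cfg6)$values
  adj <- vapply(1:59, function(j) cor(G6[, j], G6[, j + 1]), 0)
  within <- adj[(1:59) %% 10 != 0]   # adjacent pairs inside a block
  across <- adj[(1:59) %% 10 == 0]   # pairs straddling a block boundary
  expect_gt(mean(within), 0.3)       # attenuated relative to latent 0.6
  expect_lt(mean(abs(across)), 0.1)
})

test_that("missingness is generated at the configured rate and imputable", {
  cfg <- sim_config(n_samples = 500, n_markers = 200, missing_rate = 0.1,
                    seed = 6)
  G <- simulate_genotypes(cfg)
  expect_equal(mean(is.na(G$values)), 0.1, tolerance = 0.05)
  Gc <- impute_marginal(G, seed = 1)
  expect_false(anyNA(Gc$values))
  expect_identical(Gc$values[!is.na(G$values)], G$values[!is.na(G$values)])
  expect_identical(impute_marginal(G, seed = 1)$values, Gc$values)
})

test_that("trait simulation hits the heritability limits exactly", {
  cfg1 <- sim_config(n_samples = 300, n_markers = 80, n_traits = 2,
                     n_qtl_shared = 8, heritability = 1, ld_rho = 0, seed = 7)
  G <- simulate_genotypes(cfg1)
  st <- simulate_traits(G, cfg1)
  # h2 = 1: traits are exactly the standardized genetic values
  Z <- scale(G$values)
  Z[, !is.finite(colSums(Z))] <- 0
  gv <- Z %*% st$truth$effects
  expect_equal(unname(st$traits$values), unname(apply(gv, 2, scale)),
               tolerance = 1e-12)

  cfg0 <- sim_config(n_samples = 2000, n_markers = 100, n_traits = 1,
                     n_qtl_shared = 5, heritability = 0, ld_rho = 0, seed = 8)
  G0 <- simulate_genotypes(cfg0)
  st0 <- simulate_traits(G0, cfg0)
  cors <- abs(cor(st0$traits$values[, 1], G0$values))
  expect_lt(max(cors), 0.1)  # pure noise: no marker association

  expect_error(simulate_traits(simulate_genotypes(
    sim_config(n_samples = 50, n_markers = 20, missing_rate = 0.2, seed = 1)),
    sim_config(n_samples = 50, n_markers = 20, missing_rate = 0.2, seed = 1)),
    class = "mtgwp_precondition_error")
})

test_that("heritability calibration holds at moderate sample size", {
  cfg <- sim_config(n_samples = 2000, n_markers = 300, n_traits = 2,
                    n_qtl_shared = 10, heritability = c(0.6, 0.3),
                    ld_rho = 0.2, seed = 9)
  st <- simulate_traits(simulate_genotypes(cfg), cfg)
  expect_equal(st$truth$realized_h2, c(0.6, 0.3), tolerance = 0.05)
  # regression of the trait on the true causal standardized markers
  Z <- scale(simulate_genotypes(cfg)$values)
  fit <- lm(st$traits$values[, 1] ~ Z[, st$truth$causal_indices[[1]]])
  expect_equal(summary(fit)$r.squared, 0.6, tolerance = 0.05)
})

test_that("four-class recoding follows the 2*b1 + b2 mapping with > 0 rule", {
  expect_identical(liability_to_fourclass(rbind(c(-0.3, 0.7)))$values, 1L)
  expect_identical(liability_to_fourclass(rbind(c(0, 0)))$values, 0L)
  expect_identical(liability_to_fourclass(rbind(c(0.5, -1)))$values, 2L)
  expect_identical(liability_to_fourclass(rbind(c(2, 3)))$values, 3L)

  Y <- matrix(abs(rnorm(40)) + 0.1, ncol = 2)
  lab <- liability_to_fourclass(Y)
  expect_identical(tabulate(lab$values + 1L, 4L), c(0L, 0L, 0L, 20L))

  expect_error(liability_to_fourclass(matrix(1, 3, 3)),
               class = "mtgwp_precondition_error")

  # composing with the inverse mapping recovers the binary pair exactly
  Y2 <- matrix(rnorm(60), ncol = 2)
  lab2 <- liability_to_fourclass(Y2)
  expect_identical(fourclass_to_binary(lab2),
                   cbind(b1 = (Y2[, 1] > 0) * 1L, b2 = (Y2[, 2] > 0) * 1L))
})

test_that("MAF filtering removes rare markers and conserves the rest", {
  G <- genotype_matrix(cbind(a = c(1L, 1L, 1L, 1L), b = c(0L, 0L, 0L, 1L)),
                       coding = "additive_012")
  res <- maf_filter(G, 0.2)
  expect_identical(res$genotypes$marker_ids, "a")  # MAFs 0.5 and 0.125
  expect_identical(res$removed, "b")
  expect_identical(maf_filter(G, 0)$genotypes$values, G$values)
  expect_identical(sort(c(maf_filter(G, 0.2)$genotypes$marker_ids,
                          maf_filter(G, 0.2)$removed)), sort(G$marker_ids))
  Grare <- genotype_matrix(cbind(a = c(0L, 0L, 0L, 1L), b = c(0L, 0L, 0L, 1L)))
  expect_warning(res2 <- maf_filter(Grare, 0.3), "all markers")
  expect_identical(ncol(res2$genotypes$values), 0L)
  # threshold exactly at a marker's MAF keeps it (strictly-below rule)
  expect_identical(maf_filter(G, 0.5)$genotypes$marker_ids, "a")
  # MAF computed on non-missing entries only: a -> f = 1, MAF 0; b -> MAF 0.25
  Gm <- genotype_matrix(cbind(a = c(2L, 2L, NA, 2L), b = c(0L, 0L, 0L, 2L)))
  expect_identical(maf_filter(Gm, 0.2)$removed, "a")
})

test_that("marginal imputation draws from each marker's observed codes", {
  G <- genotype_matrix(cbind(a = c(0L, 0L, 0L, 0L, NA)))
  expect_identical(impute_marginal(G, seed = 3)$values[5, 1], 0L)

  n_miss <- 10000
  vals <- c(rep(c(0L, 2L), 50), rep(NA_integer_, n_miss))
  Gb <- genotype_matrix(matrix(vals, ncol = 1))
  imp <- impute_marginal(Gb, seed = 4)$values[-(1:100), 1]
  expect_equal(mean(imp == 2L), 0.5, tolerance = 0.02)

  Gf <- genotype_matrix(cbind(ok = c(0L, 1L), bad = c(NA, NA)))
  expect_error(impute_marginal(Gf), "bad", class = "mtgwp_data_error")
})

test_that("70/10/20 splits have exact rounded sizes and are reproducible", {
  sp <- split_data(10, c(0.7, 0.1, 0.2), seed = 1)
  expect_identical(lengths(sp[c("train_idx", "val_idx", "test_idx")]),
                   c(train_idx = 7L, val_idx = 1L, test_idx = 2L))

  sp2 <- split_data(1814, c(0.7, 0.1, 0.2), seed = 1)
  all_idx <- c(sp2$train_idx, sp2$val_idx, sp2$test_idx)
  expect_identical(sort(all_idx), 1:1814)
  expect_identical(anyDuplicated(all_idx), 0L)

  expect_identical(split_data(100, seed = 5), split_data(100, seed = 5))
  expect_false(identical(split_data(100, seed = 5)$train_idx,
                         split_data(100, seed = 6)$train_idx))
  expect_error(split_data(3, c(0.7, 0.1, 0.2)), class = "mtgwp_config_error")
  expect_error(split_data(100, c(0.5, 0.2, 0.2)), class = "mtgwp_config_error")
})
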