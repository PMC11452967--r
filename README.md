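# mtgwp — multi-trait genome-wide prediction with sparse neural networks

Genome-wide prediction estimates phenotypes or genetic merit from a panel of
SNP markers: an `n x p` dosage matrix (codes 0/1/2, or 0/1 for dominant
markers) against `k` correlated traits or a multi-class label, with far fewer
samples than markers. This package is for quantitative geneticists and
breeders who want non-linear multi-trait prediction *with* interpretable
marker selection in that `n << p` regime.

At its core is a **multi-task LassoNet**: a residual network

    Y_hat = theta' X + g_W(X)

whose linear skip connection `theta` (p x k) carries an L1 penalty
`lambda * ||theta||_1` under the hierarchy constraint

    || W_i^(1) ||_inf  <=  nu * sel(theta_i),   i = 1..p,

tying each marker's first-hidden-layer weights to its skip coefficients: a
marker can act non-linearly only if it is active linearly, so skip sparsity
controls feature sparsity for the whole network. `nu = 0` recovers exactly
the Lasso; `nu = Inf` recovers a plain multi-task MLP. Training follows a
dense-to-sparse regularization path — a dense warm start at `lambda = 0`,
then geometric `lambda` steps in which every gradient update is followed by
an exact **hierarchical proximal operator** (soft-thresholding of the skip
row coupled to clamping of the hidden row, solved in `O((h+k) log(h+k))` per
feature in C++). The package also implements **GANDALF** (stacked gated
feature learning units with learnable sparse feature masks and GRU-style
gates), gradient-boosting and MLP baselines, the evaluation metrics
(MSE, mean Pearson r, accuracy, macro AUC, multi-class Brier) with 10-seed
ensembling, TPE Bayesian hyperparameter search scored by 5-fold
cross-validation, and a synthetic genotype–phenotype simulator (blockwise
LD, pleiotropic QTL architectures, target heritability, MAF filtering,
marginal-distribution imputation, 70/10/20 splits, four-class recoding of
liability traits).

## Worked example

Simulate a mice-like panel (400 samples, 1000 markers, 2 traits sharing 15
pleiotropic QTLs at heritability 0.6), fit the LassoNet path, and inspect
the selected markers:

```r
library(mtgwp)

cfg <- sim_config(n_samples = 400, n_markers = 1000, n_traits = 2,
                  n_qtl_shared = 15, heritability = 0.6, ld_rho = 0.3,
                  seed = 42)
G   <- simulate_genotypes(cfg)
sim <- simulate_traits(G, cfg)
sp  <- split_data(cfg$n_samples, c(0.7, 0.1, 0.2), seed = 42)

lcfg <- lassonet_config(task = "regression", nu = 10, path_multiplier = 1.2,
                        epochs_dense = 150, epochs_per_step = 8,
                        learning_rate = 0.01, seed = 1)
path <- fit_path(G, sim$traits, sp, lcfg)
best <- select_model(path)
print(path)
#> <lassonet_path> 29 points, lambda 9.45..1.56e+03, best support 22 (val metric 0.6537)
print(selected_features(best$model))
#> <selection_report> markers selected per trait:
#>   T1: 11
#>   T2: 11

Xte  <- G$values[sp$test_idx, ]
Yte  <- sim$traits$values[sp$test_idx, ]
pred <- predict(best$model, Xte)
mse_mean(Yte, pred)        # 0.590
pearson_r_mean(Yte, pred)  # 0.721
```

The validation-optimal path point keeps 22 of 1000 markers; those include
93% of the planted QTLs, and the test MSE (traits are z-scored, so 1.0 is
the trivial baseline) beats the boosted-tree comparator on the same split
(`fit_gbdt_baseline(...)` gives 0.947). `run_benchmark()` wraps this loop —
model list, 10 seeds, ensembled metrics — into one JSON report, and
`inst/cli/mtgwp` exposes `simulate`/`fit`/`eval` subcommands for shell use.

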