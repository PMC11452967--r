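---
title: "Multi-trait genome-wide prediction with sparse neural networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait genome-wide prediction with sparse neural networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtgwp)
```

## The problem

Genome-wide prediction (GWP) estimates phenotypes or genetic merit from a
panel of SNP markers: an $n \times p$ dosage matrix $X$ (codes 0/1/2, or 0/1
for dominant markers such as DArT assays) and $k$ correlated traits
$Y \in \mathbb{R}^{n \times k}$, or a single multi-class label per sample.
The defining difficulty is $n \ll p$: hundreds to a few thousand individuals
against thousands to tens of thousands of markers. Linear mixed models and
penalized regressions are the field's workhorses; neural networks promise to
capture non-additive (epistatic) signal but need strong, structured
regularization to survive the $n \ll p$ regime. This package implements two
such architectures for multi-task (multi-trait) GWP — a multi-task LassoNet
and a gated adaptive network (GANDALF) — together with the supporting
protocol: a synthetic genotype–phenotype generator, quality-control
operations, evaluation metrics with seed ensembling, cross-validated
Bayesian hyperparameter search, and boosted-tree / MLP baselines.

## Multi-task LassoNet

The model is a residual network

$$\hat{Y} = \theta^{\top} X + g_W(X),$$

a linear *skip connection* with coefficients $\theta \in \mathbb{R}^{p \times k}$
plus a fully connected feed-forward network $g_W$ whose hidden layers are
shared by all traits and whose final linear head emits all $k$ outputs
jointly. Training minimizes the multivariate loss (mean squared error over
all $n \cdot k$ residuals, or softmax cross-entropy over $K$ classes) plus an
L1 penalty $\lambda \lVert \theta \rVert_1$, subject to the *hierarchy
constraint*

$$\lVert W^{(1)}_i \rVert_\infty \le \nu \, \mathrm{sel}(\theta_i), \qquad i = 1, \dots, p,$$

where $W^{(1)}_i$ is feature $i$'s row of first-hidden-layer weights. A
feature may act non-linearly only to the extent it is active linearly, so
zeroing a skip row removes the feature from the whole network: skip sparsity
*is* feature sparsity. Two limits anchor the model: $\nu = 0$ forces
$W^{(1)} = 0$ and the model is exactly the (multi-task) Lasso; $\nu \to
\infty$ removes the constraint and leaves a plain unregularized multi-task
MLP. Both limits are verified in the test suite — the first against a
coordinate-descent Lasso oracle (glmnet) at matched penalties, the second
against the package's own MLP baseline, which deliberately shares the
training path.

### The multi-task selection convention

The scalar-trait formulation uses $|\theta_i|$; with $k$ traits a convention
is needed. The default is **elementwise**:
$\mathrm{pen}(\theta_i) = \sum_t |\theta_{it}|$ and
$\mathrm{sel}(\theta_i) = \max_t |\theta_{it}|$ — a feature's non-linear
pathway stays open if it is selected for *any* trait, and per-trait selected
sets (what a practitioner inspects) can differ. A **grouped** convention
($\mathrm{pen} = \mathrm{sel} = \lVert \theta_i \rVert_2$, whole rows live or
die together) is available via `lassonet_config(penalty = "grouped")`. At
$k = 1$ the two coincide, which the tests assert.

### The hierarchical proximal operator

Each gradient step is followed, row by row, by the exact solution of

$$\min_{\theta_i, W_i} \tfrac12 \lVert \theta_i - b \rVert^2 +
  \tfrac12 \lVert W_i - v \rVert^2 + \lambda\,\mathrm{pen}(\theta_i)
  \quad \text{s.t.} \quad \lVert W_i \rVert_\infty \le \nu\,\mathrm{sel}(\theta_i),$$

where $(b, v)$ are the post-gradient values. Writing $M = \mathrm{sel}(\theta_i)$,
for fixed $M$ every skip coordinate is its soft-threshold
$S_\lambda(x) = \mathrm{sign}(x)\max(|x| - \lambda, 0)$ capped at $M$ (with
the cheapest coordinate — the largest $|b_t|$ — pushed up to $M$ when $M$
exceeds the unconstrained maximum), and every hidden weight is $v_j$ clamped
to $[-\nu M, \nu M]$. The resulting one-dimensional objective in $M$ is
convex piecewise quadratic; its minimizer is found exactly by an ascending
sweep over the sorted $O(h + k)$ breakpoints (implemented in C++ for all $p$
rows at once). The operator can *raise* a skip coefficient above its
soft-threshold value when that relaxes the clamp on a large hidden weight —
the k = 1 fixture in the tests (recorded from a brute-force grid/polish
minimizer before the implementation was written) shows exactly this. A
deliberate consequence of the exact solution: a zero skip row always forces
a zero hidden row.

### Dense warm start and regularization path

Training follows dense-to-sparse: first a dense model at $\lambda = 0$
(Adam, early stopping on validation loss with configurable patience; no
projection, so the $\nu = \infty$ equivalence is exact), then a geometric
penalty schedule $\lambda \leftarrow \lambda \cdot m$ (default $m = 1.02$;
coarser values like 1.15–1.35 are used in the test suite to keep runs short).
At each $\lambda$, `epochs_per_step` epochs of SGD with momentum run with the
proximal operator applied after every update; each step warm-starts from the
previous model. `lambda_start = "auto"` searches for the largest value whose
*single* proximal application drops under 5% of features, then backs off by
a further factor of 4 — one application is an underestimate of a full step's
compounded shrinkage, and without the margin a first step can collapse the
support outright.

Two design choices deserve emphasis:

* **Support monotonicity by construction.** Plain proximal steps can let a
  dropped feature re-enter (gradients at a zeroed row need not vanish). The
  path promises non-increasing support, so by default a feature whose skip
  row reaches zero is frozen for the rest of the path
  (`freeze_dropped = TRUE`). This is an algorithmic commitment, not merely an
  assertion.
* **When not to freeze.** The exact Lasso path can re-admit coordinates as
  $\lambda$ grows (correlated designs), and below the $\lambda$ at which the
  support exceeds the training-sample count the $p > n$ Lasso solution is
  not unique. The Lasso-equivalence tests therefore run the pure proximal
  path (`freeze_dropped = FALSE`) from an identifiable starting penalty;
  agreement with glmnet is then ~$10^{-6}$, far inside the documented
  $10^{-3}$ tolerance.

Model selection takes the path point with the best validation loss, exact
ties broken toward the smaller support. `selected_features()` exports the
per-trait nonzero skip coefficients — the model's built-in marker selection.

## GANDALF

The gated adaptive network stacks Gated Feature Learning Units. Stage $n$
holds a learnable mask over the $p$ markers,
$M_n = t\text{-softmax}(\mathfrak{I}_n, t_n)$, applied to the raw inputs,
$X_n = M_n \odot X$; an update gate $z_n = \sigma(W^z_n [\varphi_{n-1}; X_n])$
and reset gate $r_n = \sigma(W^r_n [\varphi_{n-1}; X_n])$ control a GRU-style
blend with the candidate
$\hat\varphi_n = \tanh(W^O_n [r_n \odot \varphi_{n-1}; X_n])$:

$$\varphi_n = (1 - z_n) \odot \varphi_{n-1} + z_n \odot \hat\varphi_n.$$

An MLP head maps the final representation to the $k$ outputs. Design choices
where the architecture description leaves room:

* the GRU combination rule above (the gated-recurrent-unit convention this
  family of models is built on);
* the reset gate mirrors the update gate's form exactly;
* $t$-softmax is implemented as temperature-scaled softmax with a per-stage
  learnable temperature (positive via a log parameterization) plus hard
  zeroing of entries below $10^{-6}$ of the maximum and renormalization —
  the sparsity-emulating part is treated as identity in the backward pass
  (straight-through);
* $\varphi_0$ is a learned linear projection of the stage-1 masked input
  (dimension `dim`, default 64);
* the candidate consumes the *masked* input $X_n$, consistent with per-stage
  feature selection;
* `n_stages = 0` degenerates to the head acting on raw (standardized)
  markers.

All gradients (gates, masks, temperatures, projection, head) are hand-derived
and verified against central finite differences to $10^{-4}$ relative; the
forward pass is verified against an independent loop-by-loop transliteration
of the stage equations to $10^{-9}$.

## The synthetic generator

No real datasets ship with the package; the generator emulates the
*structure* of the benchmark panels (mice-like 1814×10346 additive panels,
wheat-like 599×1279 dominant panels, and so on) at configurable size:

* **Allele frequencies** uniform on `maf_range` (default 0.05–0.5, matching
  the conventional MAF ≥ 0.05 QC threshold).
* **Linkage disequilibrium** via a latent Gaussian AR(1) copula inside
  blocks of `ld_block_size` markers (default 10, correlation `ld_rho`,
  default 0.3), independence across blocks. Thresholding attenuates the
  realized genotype correlation relative to the latent value (roughly 0.6
  latent → 0.4 realized for common alleles); tests therefore check the
  qualitative contrast within/across blocks and the exact independence case.
* **Architecture**: `n_qtl_shared` markers carry one effect common to all
  traits (pleiotropy — the genetic correlation that makes multi-task
  learning worthwhile), plus per-trait private markers and optional pairwise
  product (epistatic) terms. Effect magnitudes default to the equal-effects
  design (magnitude `effect_sd`, random signs): with Gaussian effects the
  smallest of, say, 20 draws carries a vanishing share of variance that *no*
  method can recover at moderate $n$, so support-recovery properties would
  measure draw luck rather than the selector. Gaussian effects remain
  available (`effect_dist = "normal"`).
* **Heritability** is imposed per trait by setting the noise variance to
  $\mathrm{var}(g)(1 - h^2)/h^2$; realized $h^2$ is within ±0.05 of target at
  $n = 2000$ (tested). $h^2 = 1$ yields exactly the standardized genetic
  values; $h^2 = 0$ drops the genetic term (the formula is singular there)
  and yields pure standardized noise.
* **Traits are z-scored** on the full sample — benchmark error magnitudes
  (test MSE well below 1) presuppose unit-variance traits, and it makes MSE
  comparable across simulated designs.
* **Missingness** is completely at random; imputation resamples each
  marker's observed marginal. The four-class recoding thresholds two
  liability-scale traits at zero (strictly greater than zero maps to 1, so
  exact zeros map to 0 — the boundary case is documented rather than left to
  chance) and encodes the pair as $2 b_1 + b_2$.

What passing tests on these data do **not** show: robustness to population
structure and kinship, realistic LD decay or allele-frequency spectra from
demography, genotyping error, informative missingness, or trait
distributions far from Gaussian. The generator is a controlled instrument
for verifying algorithmic properties, not a stand-in for real panels.

## Protocol

Samples split 70/10/20 into training/validation/test (validation and test
sizes are `round(n·f)`, the remainder goes to training — deterministic
tie-break); the test partition is untouched until final evaluation, which the
interfaces enforce by only ever handing `train_idx` to tuning code. Tuning
scores candidates by 5-fold cross-validation on the training partition
(stratified by class for classification; a class with fewer than two
training members is an error, not a silent fallback). The Bayesian optimizer
is a tree-structured Parzen estimator — after `n_init` random trials,
completed trials split at the 25% score quantile, per-parameter Parzen
densities (Gaussian kernels on the linear or log scale, smoothed frequencies
for categoricals, a 10% uniform prior for mass everywhere), candidates drawn
from the good density and ranked by density ratio — with a seeded pure-random
engine behind the same interface. The stopping rule reads "no incumbent
improvement above `tol` (default $10^{-5}$) over a sliding window of 10
trials"; the window length is this package's interpretation, since a bare
tolerance does not define one. Final evaluation trains 10 seeds, averages
their test predictions into an ensemble prediction, and reports each
metric's per-seed mean ± standard deviation alongside the ensemble-prediction
metric (the headline). Metrics: MSE over all trait residuals; Pearson $r$
averaged across traits; accuracy and one-vs-rest macro AUC on the 0–100
scale; and the original $K$-term multi-class Brier score
$\frac1n \sum_i \sum_c (p_{ic} - o_{ic})^2$ with range $[0, 2]$ (a uniform
$K = 4$ prediction scores 0.75) — benchmark Brier values in this literature
are consistent with this definition, not the halved variant, which is
available behind `normalize = TRUE`.

## Numerical choices and degenerate inputs

* Weight initialization is Glorot-uniform; skip coefficients start at zero.
  All randomness (initialization, batch order, folds, splits, simulation)
  flows through a seed-restoring wrapper, so every operation is a pure
  function of (inputs, seed); training twice with one seed is bitwise
  reproducible.
* Marker standardization uses training-partition statistics only;
  zero-variance (monomorphic) columns get scale 1 (and contribute nothing).
* Divergence (non-finite loss) raises an error naming the learning rate
  rather than returning garbage.
* The proximal sweep treats ties among breakpoints exactly (closed-form
  stationary points per interval); `nu = 0` and `nu = Inf` short-circuit.
* Empty-support paths, empty selection reports, all-markers-removed MAF
  filtering (warning + empty matrix), fully missing markers (error naming
  the marker), and constant trait columns in `pearson_r_mean` (error naming
  the trait) are all handled explicitly.
* Problem sizes in the test suite are the package's own verification sizes,
  chosen so each property is measurable with margin: 1000 random instances
  for the proximal oracle ($h \le 8$, $k \le 3$); $200 \times 500$ for the
  Lasso limit; $500 \times 2000$ markers, 3 traits, 20 shared QTLs at
  $h^2 = 0.6$ for support recovery (≥80% of planted QTLs at the
  validation-optimal point, and median test MSE at or below the boosted-tree
  baseline over 5 seeds); $n = 2000$ for heritability calibration.

## Known limitations

* Training is plain R matrix algebra (BLAS) plus the C++ proximal kernel —
  adequate for $p$ in the low tens of thousands, not for biobank scale.
* The default path multiplier 1.02 is faithful but slow; coarser multipliers
  trade path resolution for speed and are what the tests use.
* The TPE implementation is univariate per parameter (no tree structure over
  conditional spaces) — sufficient for the search spaces shipped here.
* GANDALF's mask sparsification is an emulation (clip + renormalize);
  exactly sparse simplex activations would require the specialized
  activation's exact form, which is outside this package's sources.
* `fit_gbdt_baseline` requires the xgboost package and errors informatively
  without it; folds run sequentially (results are order-independent, so a
  parallel backend could be added without changing contracts).
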