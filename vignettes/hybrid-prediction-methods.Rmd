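---
title: "Predicting hybrid yield in unbalanced testcross factorials: models, tuning and benchmarks"
author: "hybfact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hybrid yield in unbalanced testcross factorials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybfact)
```

## The problem

Hybrid breeding crosses inbred lines from two parent groups and selects on
the yield of the resulting hybrids. Early-stage programs can field-test
only a small, skewed subset of the possible crosses: factorials are
*incomplete* (often < 15% of cells realized) and *unbalanced* (some
parents appear in hundreds of crosses, others in one or two). Where no
heterotic pattern has been established, specific combining ability (SCA)
— the deviation of a cross from the sum of its parents' general combining
abilities (GCA) — contributes a large share of the genetic variance,
which blunts classical GCA-based selection.

`hybfact` implements, under one roof and one cross-validation protocol,
the three families of predictors that compete in this setting:

1. **Combining-ability BLUP** on adjusted entry means,
2. **GBLUP** with genomic GCA kernels and a Kronecker-product SCA kernel,
3. **Machine-learning regressors** on parentage, cross-yield or marker
   predictors, capped by a **stacked ensemble of gradient boosting
   machines** with a ridge super learner,

plus a synthetic factorial generator so that every stage is testable
without confidential field data.

## The combining-ability model

For the hybrid of group-1 parent $i$ and group-2 parent $j$,

$$ y_{ij} = \mu + \mathrm{GCA1}_i + \mathrm{GCA2}_j + \mathrm{SCA}_{ij}, $$

with both GCA terms as crossed random intercepts estimated by REML
(`fitGcaBlup()`, backed by `lme4`; tiny or degenerate designs fall back
to a dense derivative-free REML on the same model). With a single
adjusted entry mean per hybrid the SCA term is **not separable from the
residual**: the model reports the residual variance as
$\sigma^2_{\mathrm{SCA}}$, flags $\sigma^2_e$ as confounded, and defines
$\mathrm{SCA}_{ij}$ as the raw residual
$y_{ij} - \hat\mu - \widehat{\mathrm{GCA1}}_i - \widehat{\mathrm{GCA2}}_j$.
This is the only identifiable reading of the model on entry means, it
makes the decomposition exact on every realized cross, and it matches the
convention of reporting a single SCA variance per factorial. The summary
statistic

$$ \tau = \frac{\sigma^2_{\mathrm{SCA}}}{\sigma^2_{\mathrm{GCA1}} +
\sigma^2_{\mathrm{GCA2}} + \sigma^2_{\mathrm{SCA}}} $$

(`computeTau()`) separates GCA-dominated factorials ($\tau \lesssim 0.2$)
from SCA-dominated ones ($\tau \gtrsim 0.5$). Prediction for an untested
cross is $\hat\mu + \widehat{\mathrm{GCA1}}_i + \widehat{\mathrm{GCA2}}_j$;
the SCA deviation is unpredictable from phenotype alone and reverts to
its prior mean. The raw-residual (unshrunken) convention is also used for
the reported $r(\mathrm{SCA}, y)$ correlation; a shrunken alternative
would only attenuate that correlation.

## GBLUP with a Kronecker SCA kernel

With inbred parents genotyped at biallelic SNPs coded $-1/1$,
`vanRadenG()` builds per-group relationship matrices
$G = WW'/c$, $w_{uv} = x_{uv} + 1 - 2p_v$, $c = 2\sum_v p_v(1-p_v)$,
with allele frequencies $p_v$ estimated *within parent group* from the
filtered, pre-imputation panel (so each row of $G$ sums to zero).
Markers are removed when expected heterozygosity $2p(1-p) < 0.10$ or
missingness exceeds 1%, and remaining gaps are mean-imputed — the
standard pre-processing for this model class.

`fitGblup()` fits
$y = \mathbf{1}\beta_0 + Z_1 g_1 + Z_2 g_2 + Z_S s + e$ with
$\mathrm{var}(g_k) = \sigma^2_k G_k$ and
$\mathrm{var}(s) = \sigma^2_s S$, where $S$ is $G_1 \otimes G_2$
restricted to realized hybrids. $S$ is assembled **entry-wise** from
$S_{(ij),(kl)} = G_1[i,k]\,G_2[j,l]$; the full Kronecker product (which
would be $18144^2$ for the largest published factorial) is never
materialized. Prediction of arbitrary pairs — including parents with no
training crosses — is multivariate-normal conditioning:
$\hat y = \beta_0 + \mathrm{cov}(\text{target},\text{train})
V^{-1}(y - \beta_0)$.

Numerical choices: a jitter of $10^{-6}$ on the $G$ diagonals before
factorization (VanRaden matrices from few markers are often
rank-deficient); REML by Nelder–Mead over log-variances (derivative-free,
components bounded below at $10^{-12}$), relative log-likelihood
tolerance $10^{-8}$, at most 1000 evaluations; a flat response puts all
components at the lower bound with $\beta_0 = \bar y$. The same REML core
drives the Gaussian multi-kernel (RKHS) learner.

## Predictor encodings for the ML layer

Three predictor sets (`FeatureTable` objects):

* **Parentage** — only the two parent identities, as nominal factors or
  one-hot indicators (`encodeParentage()`).
* **Cross yields** — one column per parent line; for hybrid $(i,j)$ the
  column of group-2 parent $q$ holds the observed yield of $(i,q)$
  (`encodeYieldFeatures()`). The hybrid's own yield never appears in its
  row, and all response yields of a prediction split are excluded before
  encoding. In sparse factorials these tables are mostly missing by
  construction; columns that end up constant or all-missing are dropped
  and logged.
* **Virtual hybrid genotypes** — parent-dosage midpoints
  $(x_{1v} + x_{2v})/2 \in \{-1, 0, 1\}$ (`encodeHybridGenotypes()`),
  optionally concatenated with parentage (`combineFeatures()`).

For tree learners, parent factors are encoded by a *smoothed
target statistic*: level means pulled toward the grand mean with an
empirical-Bayes m-estimate ($m = 5$ effective observations). Parents with
one or two crosses would otherwise dominate the encoding with noise.
Gradient boosting then bins the encoded values with its histogram
control (`max_bin` = the `nbins_cats` hyperparameter); random forest,
whose backend has no bin control, gets the same effect from
equal-frequency collapsing of the encoded levels. Missing predictor
values pass natively to gradient boosting; all other learners (including
random forest, whose backend requires complete data) receive
training-column-mean imputation.

## Base learners and their hyperparameter spaces

`fitPredict()` gives a uniform seed-deterministic interface over:
gradient boosting (`gb`, xgboost backend, learning rate fixed at 0.1), a
marker-mode booster (`gb-marker`, 1000 trees with early stopping at
patience 10 on a 10% validation split, tuned learning rate, pruning
gamma, per-tree column subsampling), random forest (`rf`, ranger),
support vector regression (`svm`, e1071), a Gaussian multi-kernel ridge
(`rkhs`, bandwidths 0.1/0.5/2.5 on the mean-scaled squared Euclidean
marker distance, kernel weights by REML — a deterministic stand-in for
Bayesian kernel averaging over the same function class), and a
from-scratch SGD matrix factorization (`mf`, learning rate fixed at
0.05, 500 iterations, L1 penalties, no bias terms; the response is
grand-mean-centered in the wrapper).

The tunable spaces (`defaultHyperparameterSpace()`) span each
algorithm's named controls with deliberately wide ranges — optimal
values are known to sit at both ends of the range in some factorials:

| algorithm | tuned | fixed |
|---|---|---|
| gb / rf | trees 50–800, depth 2–12, min rows 1–20, row sample 0.5–1, bins 8–1024 | learn rate 0.1 (gb) |
| gb-marker | learn rate 0.01–0.3, gamma 0–10, column sample 0.3–1 | 1000 trees + early stopping |
| svm | C 0.1–100, epsilon 0.01–0.5, kernel linear/radial/poly(2–4) | — |
| mf | dim 2–64, L1 costs 0–0.1 | lrate 0.05, 500 iters |

The `mf` dimension list includes 64 so that every tunable space has at
least 50 Cartesian combinations, the contract the random grid search
assumes.

## Random grid search and the stacked ensemble

`runGridSearch()` draws up to 50 hyperparameter combinations uniformly
without replacement and scores each with the *same* random 10-fold
partition by out-of-fold MSE; the lowest MSE wins (ties: first drawn).
Failed fits are flagged and excluded, never imputed.

`buildStackedEnsemble()` ranks the models by CV MSE and, for each
candidate size $k \in \{5, 10, \dots, 50\}$, trains a ridge super
learner on the **out-of-fold** predictions of the top $k$ — the
leakage-safe reading of stacking, since no base model's in-fold fit ever
reaches the ridge. The penalty is chosen by internal 5-fold CV over a
geometric grid $10^{-4}\dots10^{2}$ (on the glmnet scale; the source did
not state its selection rule, so this choice is documented here). Each
$k$ is scored by the Pearson correlation between the response and the
super learner's own out-of-fold predictions, reusing the grid-search
folds; the best $k$ wins, ties to the smallest. Constant predictions
score 0 with a warning. Non-negative super-learner weights are available
behind `nonneg = TRUE` (default off; whether the original metalearner
constrained signs is unknown).

## Cross-validation protocol and metrics

`makeCvSplits()` draws 100 (default; 20 at desk scale) random 90/10
splits. Test hybrids with fewer than two parents represented in the
training crosses are moved to a `removed` set — combining-ability
prediction needs both parents trained. A split whose filtered test set
comes out empty is regenerated with a perturbed sub-seed (logged, at
most 10 attempts); the protocol's source is silent on this corner.
Metrics are *prediction accuracy* — the Pearson correlation
$r(y, \hat y)$ on the filtered test set — and the percentage overlap of
the top-20 predicted vs. observed hybrids (`topKOverlap()`, stable-order
tie-breaking). `runBenchmark()` re-runs every stage per split (REML
refits; a fresh grid search and stacking inside each training set),
rebuilds yield-feature encodings from training yields only, reports
per-split rows plus per-algorithm medians, and flags algorithms failing
more than half their splits.

## The synthetic generator

`simulationConfig()` + `simulateDataset()` emulate the statistical
structure the models assume: two parent groups, a weighted-without-
replacement crossing design with per-parent weights $\propto
\mathrm{rank}^{\mathrm{skew}}$ (repaired so every parent is covered;
skew ≈ 1 reproduces the long-tailed per-parent cross counts of real
early-stage factorials), i.i.d. Gaussian GCA/SCA effects with
configurable variances, and additive measurement noise drawn separately
from SCA so tests know the truth even though an entry-mean analysis
cannot split them. Under `architecture = "marker-driven"`, homozygous
$-1/1$ panels are drawn with uniform allele frequencies on `maf_range`
and the effects are *rebuilt from the panels*: $\mathrm{GCA}_i = \sum_v
a_v x_{iv}$ (centered within group), $\mathrm{SCA}_{ij} = \sum_v d_v
[x_{iv} \neq x_{jv}]$ (dominance on heterozygous hybrid loci), with $a$
and $d$ Gaussian and rescaled so the realized variances equal the
configured components. `architecture = "effects-direct"` keeps markers
independent of the effects — a negative-control panel.

What the generator does **not** emulate — and hence what passing
benchmarks do and do not show: linkage and LD structure, multi-
environment trials, heterozygous parents, and *structured* SCA. The
generated SCA of a cross is independent noise given the parents (or
dominance on independent loci), whereas in real factorials related
parent combinations share SCA. Parentage-based learners therefore
cannot beat combining-ability BLUP on these data — the additive part is
exactly what BLUP estimates optimally — so the synthetic benchmark
asserts *equivalence within tolerance* in the high-$\tau$ condition and
equivalence of GBLUP and GCA in the low-$\tau$ marker condition, a
directional mirror of the published pattern rather than a reproduction
of its accuracy gains.

## Problem sizes and reference conditions

The packaged checks run at desk scale, chosen to finish on one CPU while
keeping the statistics stable: variance-recovery studies use 60 × 20
parents, 600 crosses, 200 markers, 20 seeds (the default
`simulationConfig()`, $\tau = 0.5$, $\sigma^2_e = 0$ because the
entry-mean model folds noise into SCA); the high-$\tau$ benchmark uses
60 × 14 parents and 750 crosses with the published rapeseed variance
components (0.516, 0.774, 2.663; $\tau = 0.67$); the low-$\tau$
benchmark uses 50 × 41 parents and 550 crosses with the published corn
components (73.05, 24.39, 15.78; $\tau = 0.14$), 200 markers,
$\sigma^2_e = 10$. Benchmarks run 20 splits; the full protocol (100) is
one argument away.

## Known limitations

* The GCA model's $\sigma^2_{\mathrm{SCA}}$ is only interpretable as SCA
  variance to the extent that genuine measurement error is small;
  $\tau$ estimated from entry means is biased upward by that error.
* The published supplementary hyperparameter grids were not available;
  the spaces above are documented replacements, not reconstructions.
* REML on dense kernels scales as $O(n^3)$ per likelihood evaluation;
  factorials beyond a few thousand crosses need a sparse or
  low-rank refit.
* Matrix factorization and parentage learners cannot predict hybrids
  whose parents never appear in training (type-0/1 hybrids); the
  marker route (`predictGblup`, `gb-marker`, `rkhs`) can.

```{r example, eval = FALSE}
# a compact end-to-end run
cfg <- simulationConfig(n1 = 30, n2 = 10, n_crosses = 200, n_markers = 100,
                        architecture = "marker-driven", seed = 1)
ds <- simulateDataset(cfg)
describeFactorial(ds$factorial)
sol <- fitGcaBlup(ds$factorial)
varianceComponents(sol)
bench <- runBenchmark(ds$factorial,
                      markers = list(panel1 = ds$panel1, panel2 = ds$panel2),
                      algorithms = c("gca", "gblup", "gb-se"),
                      config = benchmarkConfig(nSplits = 5, seed = 1))
bench$medians
```
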