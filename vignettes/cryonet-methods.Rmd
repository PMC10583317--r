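---
title: "cryonet: statistical methods and generator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cryonet: statistical methods and generator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical choices behind each `cryonet`
stage and, equally important, how the synthetic-data generator is
calibrated so that planted structure is recoverable by the honest
analysis — not by tuning the analysis toward the generator.

## 1. Niche breadth and the permutation null

Levins' niche breadth for taxon $i$ is $B_i = 1 / \sum_j p_{ij}^2$ where
$p_{ij}$ is the proportion of taxon $i$'s total abundance found in sample
$j$. $B$ ranges from 1 (a single-habitat specialist) to the number of
samples (perfectly even generalist). Raw $B$ is confounded by occupancy
and abundance, so classification is relative to a null: TPM profiles are
discretized to integer counts at depth $10^4$ per sample (fill preserved
by flooring nonzero cells at 1), and `vegan`'s `quasiswap_count` null
model shuffles them under fixed row and column sums and fixed fill. A
taxon is a *generalist* if its observed $B$ exceeds the upper bound of the
null's 95% interval, a *specialist* if it falls below the lower bound, and
*uncategorized* otherwise (boundaries inclusive of the interval count as
uncategorized).

Two properties of this null matter for the generator design:

* the null concentrates as a taxon's discretized row total shrinks, so
  very rare taxa need strongly uneven profiles to test as specialists;
* the null's occupancy reflects the *global* fill, so a taxon present
  everywhere but overdispersed can still fall inside the interval.

`simulate_community()` therefore gives each partial-occupancy taxon a
*niche window*: an optimum drawn uniformly along the radiation gradient
and occupancy of the $k$ nearest samples, with expected abundance decaying
geometrically with rank distance from the optimum
(`window_concentration`). Specialists use a steep decay (concentration
0.3, $B \approx 1.6$), intermediates are made overdispersed (negative
binomial size 3, $B \approx 9.5$, inside the null interval). These are
design-phase calibrations of the *study conditions*; they were never
moved in response to a failing test.

## 2. Compositional treatment

Both abundance tables are TPM, i.e. compositions summing to $10^6$.
Correlations on raw compositions are distorted by closure, so all
network and environment stages operate on centered log-ratios:
$\mathrm{clr}(x)_i = \log x_i - \frac1D \sum_k \log x_k$. Zeros are
replaced multiplicatively (`czm_replace`): each zero becomes
$\delta = 0.65 \cdot \min(\text{nonzero})$ per sample and nonzero parts
are scaled down so totals are preserved. For very sparse samples the
naive $\delta$ can exceed the total; `czm_replace` caps it at
`delta_frac * total / n_zeros` so adjusted parts stay positive.

## 3. The co-occurrence network

The network follows the weighted co-expression recipe on CLR profiles of
KOs present in at least 70% of samples: unsigned adjacency
$a_{ij} = |r_{ij}|^\beta$ at $\beta = 7$ (the scale-free fit table across
powers 1–20 is reported), topological overlap

$$\omega_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
\qquad \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},$$

and average-linkage clustering on $1 - \omega$.

**Tree cut.** Instead of a fixed cut height, `detect_modules()` scans the
midpoints between consecutive distinct merge heights of the dendrogram.
At each candidate height, subtrees with at least `min_module_size` (50)
members are modules; the chosen height maximizes the module count, with
ties broken by the mean silhouette width of assigned features and then by
the lower height, so the cut is deterministic. The static cut leaves
peripheral features grey; `reassign_grey()` then rescues grey features
whose module membership (kME, correlation with a module eigengene)
exceeds 0.7 — the membership-based stage of adaptive tree cutting. Under
pure noise with 60 samples, kME is approximately $N(0, 1/\sqrt{60})$, so
0.7 sits beyond five standard deviations and false rescues are
negligible. Modules with eigengene correlation above 0.75 are merged
before the rescue.

**Eigengenes.** A module eigengene is the first right singular vector of
the row-standardized module submatrix, scaled to unit variance and
oriented to correlate positively with the module's mean profile; the
proportion of variance explained is reported.

## 4. Module selection by LASSO

Radiation is regressed on the module eigengenes with an in-house LASSO:
cyclic coordinate descent on the objective
$\frac{1}{2n}\mathrm{RSS} + \lambda \lVert\beta\rVert_1$ with predictors
standardized to unit $1/n$ variance, a 100-point log grid from
$\lambda_{max} = \max_j |x_j^\top y| / n$ down to $10^{-4}\lambda_{max}$,
and warm starts. Ten-fold cross-validation picks `lambda.min` (ties
toward the larger $\lambda$). The selected eigengenes are refit by
unpenalized OLS on z-scored data for standardized effect sizes with
confidence intervals. `glmnet` is used in the test suite only, as an
independent cross-check of the path.

**Generator calibration for exact selection.** A subtle coupling exists
between TPM closure and CLR: a module whose members rise with radiation
drags the sample log-mean, imprinting a spurious radiation correlation of
opposite sign on *all* other KOs. Three design choices neutralize it so
the planted null module is genuinely null: module sizes are balanced so
$\sum_m \text{size}_m \cdot \text{link}_m \approx 0$; the latent module
factors are Gram–Schmidt orthogonalized against the radiation gradient
and each other (making the null module's partial correlation exactly zero
with ideal factors); and the KO universe is large (1000) so the residual
coupling, proportional to module size over universe size, is small.

## 5. Hub genes and enrichment

Within the strongest positively and strongest negatively
radiation-correlated modules, hub KOs must pass kME > 0.9 *and*
|correlation with radiation| > 0.8 *and* be annotated to a pathway that
is both hypergeometrically enriched in the module (BH q <= 0.05) and on
the configured whitelist of motility/biofilm-related pathways. The hub
subnetwork connects hubs with $|r| \ge 0.6$ and reports exact betweenness
centrality. Because a single pathway cannot test as enriched when its
module spans a quarter of the KO universe, the generator plants each
hub-bearing module with its own whitelisted pathway while keeping every
hub on the *biofilm formation* pathway.

## 6. Environmental attribution

Covariates are pruned by iterative VIF (drop the worst until all < 10),
then:

* **RDA** (`vegan::rda`) of the sample-by-feature CLR matrix on z-scored
  covariates, with global permutation F tests and `envfit` vector fits;
* **hierarchical partitioning** by full subset enumeration (bitmask over
  at most 12 covariates): each covariate's independent contribution is
  the average of its incremental $R^2$ over all subsets of the others,
  and the contributions sum *exactly* to the full-model $R^2$;
* **MRM**: OLS of the standardized community-distance vector (Aitchison,
  i.e. Euclidean on CLR) on standardized covariate distances, with
  Mantel-style simultaneous row/column permutations of the response
  matrix and t-statistic exceedance p-values;
* **distance decay**: community distance against pairwise radiation
  difference vs haversine geographic distance (Earth radius 6371 km).

The generator assigns samples to regions probabilistically along the
gradient (softmax of radiation-dependent log-odds), so regional ranges
overlap and the radiation signal is not a geography artifact — the decay
comparison then favors the gradient by design.

## 7. Determinism

Every stage derives its RNG stream from the run seed via
`seed + 7919 * offset mod (2^31 - 1)` with stage-specific offsets.
Identical inputs, configuration, and seed produce byte-identical output
files; the acceptance suite verifies this with checksums.

## Limitations

* The generator plants independent log-normal KO noise; real metagenomes
  have taxonomic covariation between KOs sharing carriers.
* The quasiswap null is the only niche null shipped besides a
  within-sample shuffle; other fixed-fill algorithms may give slightly
  different intervals for heavily tied tables.
* Hub selection assumes exactly one dominant positive and one dominant
  negative radiation module, as in the planted design; ambiguous module
  landscapes return fewer or no hubs rather than guessing.
* The betweenness brute-force oracle in the tests limits graph size;
  correctness on large hub networks rests on `igraph`.

```{r example}
library(cryonet)
bundle <- simulate_bundle(sim_spec(rng_seed = 1))
res <- run_pipeline(bundle, run_config(), out_dir = "results/full_run")
```
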