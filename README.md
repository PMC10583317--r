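# cryonet

Post-annotation analysis of glacier cryoconite metagenomes: who are the
habitat generalists and specialists, how do functional genes organize into
co-occurrence modules, and which meteorological forces structure both.

Cryoconite — the dark sediment dotting glacier surfaces — hosts dense
microbial communities living along steep gradients of solar radiation.
`cryonet` takes the standard products of a metagenome pipeline (a
species-level genome bin (SGB) abundance table in TPM, a KEGG-ortholog (KO)
abundance table, genome annotations, and per-sample meteorology) and runs
the full downstream analysis:

1. **Niche breadth** — Levins' index per taxon, classified against a
   fixed-margin permutation null (quasiswap on discretized counts) into
   generalists, specialists, and uncategorized taxa.
2. **Genome features** — genome size, GC content, and gene redundancy
   contrasts between classes (exact Wilcoxon for small groups), plus a
   permutation test for differing unique-vs-total KO slopes.
3. **Co-occurrence network** — centered log-ratio (CLR) transform with
   count-zero multiplicative replacement, soft-thresholded unsigned
   adjacency, topological overlap, average-linkage tree cut with a
   silhouette-guided static height and a kME rescue stage, module
   eigengenes.
4. **Module selection** — in-house LASSO (cyclic coordinate descent,
   10-fold cross-validated lambda) picks the radiation-predictive modules;
   an unpenalized standardized refit reports effect sizes.
5. **Hub genes** — hypergeometric pathway enrichment (BH-corrected), hub
   extraction by joint kME and trait-correlation thresholds inside enriched
   whitelisted pathways, betweenness centrality, and mapping of hubs onto
   genomes.
6. **Environmental attribution** — VIF filtering, redundancy analysis with
   permutation tests, hierarchical partitioning (contributions sum exactly
   to the full-model R²), multiple regression on distance matrices, and
   distance-decay comparisons of the radiation gradient vs geography.

Because real hemispheric survey data cannot ship with a package, `cryonet`
includes a calibrated synthetic-data generator (`simulate_bundle()`) that
plants known niche classes, module structure, trait links, and hub genes,
so every stage is testable against ground truth.

## Quick start

```r
library(cryonet)

spec   <- sim_spec(rng_seed = 1)      # study-scale defaults: 60 samples,
bundle <- simulate_bundle(spec)       # 120 SGBs, 1000 KOs, 4 planted modules

# 1. niche classification (1000-permutation fixed-margin null)
niche <- classify_niche(bundle$sgb, 1000L, seed = 11L)
table(niche$class)
#>    generalist    specialist uncategorized
#>            15            66            39

# 3. KO co-occurrence network at soft power 7
net <- build_network(bundle$ko, run_config())
table(net$modules[net$modules != "grey"])
#>  blue brown turquoise yellow
#>    70    55       108     50

# module eigengenes vs solar radiation
trait <- module_trait_correlation(net$eigengenes, bundle$meteo)
subset(trait, covariate == "radiation")
#>      module  pearson_r   p_value
#>        blue      0.848   1.2e-17
#>   turquoise     -0.812   3.4e-15
#>       brown      0.475   1.3e-04
#>      yellow     -0.009   9.5e-01

# 4. LASSO module selection + standardized refit
rad <- bundle$meteo$radiation
cv  <- cv_select_lambda(net$eigengenes, rad, seed = 13L)
cv$selected
#> [1] "blue" "turquoise" "brown"
standardized_final_model(net$eigengenes[, cv$selected], rad)$adjusted_r2
#> [1] 0.794
```

On this bundle the pipeline recovers 96.7% of the planted niche labels, an
adjusted Rand index of 1.0 against the planted module blocks, all five
planted hub genes with zero false positives (`K00001`–`K00003` in the blue
module, `K00071`–`K00072` in turquoise, all on the enriched *biofilm
formation* pathway, q = 6.4e-12), and the planted module–radiation signs
(+0.83 / −0.77 / +0.45 planted vs +0.85 / −0.81 / +0.47 recovered).

The environmental stage attributes community variation to the radiation
gradient: RDA explains 20.4% of CLR community variance (permutation
p = 0.001), radiation contributes 57.7% of that explained variation under
hierarchical partitioning, and it is the only significant MRM predictor
(standardized beta = 0.319, p = 0.001). Community dissimilarity decays
faster along the radiation gradient (R² = 0.088) than with geographic
distance (R² = 0.009), and generalist unique-vs-total KO slopes exceed
specialist slopes (0.913 vs 0.780, permutation p = 0.024), reflecting the
higher gene duplication planted in specialists.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the study end to
end, writing TSV outputs (15 significant digits, with a manifest) under
`results/`:

```sh
Rscript analysis/01_simulate.R          # synthetic bundle + input tables
Rscript analysis/02_niche.R             # niche classification
Rscript analysis/03_genome_features.R   # genome feature contrasts
Rscript analysis/04_network.R           # network + modules + eigengenes
Rscript analysis/05_modules_lasso.R     # LASSO module selection
Rscript analysis/06_hubs_enrichment.R   # enrichment, hubs, hub subnetwork
Rscript analysis/07_environment.R       # RDA, partitioning, MRM, decay
```

Set `CRYONET_SEED` to change the seed (default 1). `run_pipeline()` runs
all stages in one call on in-memory inputs or files read with
`read_table()`.

## Reproduction

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "cryonet",
                               load_package = "installed")'
Rscript scripts/acceptance.R --seed 123 --out results/acceptance.json
```

The test suite includes closed-form checks, brute-force oracle
equivalences (TOM, betweenness, hypergeometric, Wilcoxon, LASSO
soft-threshold), planted-structure recovery, permutation-p calibration
under simulated nulls, the hierarchical-partitioning sum identity, and
byte-identical determinism of repeated runs. `scripts/acceptance.R` runs
the full pipeline on a seeded bundle and writes the headline quantities as
JSON.

All computation is deterministic given the seed: every stage derives its
own RNG stream from the run seed, and repeated runs produce byte-identical
outputs.

## Package layout

- `R/` — package code: `simulate.R` (generator), `niche.R`,
  `compositional.R`, `network.R`, `lasso.R`, `enrichment.R`,
  `genome_features.R`, `environment.R`, `pipeline.R`, `io.R`.
- `analysis/` — numbered workflow drivers (above).
- `scripts/acceptance.R` — seeded end-to-end run emitting JSON.
- `tests/testthat/` — unit, property, oracle, and acceptance tests.
- `vignettes/` — methods vignette describing the statistical design and
  the generator's calibration.
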