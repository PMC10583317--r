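#!/usr/bin/env Rscript
# Stage 3: genome feature contrasts between niche classes (size, GC, gene
# redundancy) and the unique-vs-total KO slope comparison.

library(cryonet)

seed <- as.integer(Sys.getenv("CRYONET_SEED", "1"))
bundle <- readRDS(file.path("results", "bundle.rds"))
niche <- readRDS(file.path("results", "niche.rds"))
cfg <- run_config(rng_seed = seed)

profiles <- genome_profiles(bundle$annotations, bundle$genomes, niche)
contrasts <- do.call(rbind, lapply(
  c("est_genome_size_bp", "gc_fraction", "redundancy_index"),
  function(f) feature_contrast(profiles, f)))
fits <- do.call(rbind, lapply(c("generalist", "specialist"), function(g) {
  if (sum(profiles$class == g, na.rm = TRUE) >= 3)
    unique_vs_total_fit(profiles, g)
}))
slope_test <- diffslope_test(
  profiles[profiles$class == "generalist", c("n_total_ko", "n_unique_ko")],
  profiles[profiles$class == "specialist", c("n_total_ko", "n_unique_ko")],
  cfg$diffslope_permutations, seed = cryonet:::derive_seed(seed, 12L))
phylum <- per_phylum_contrast(profiles, "redundancy_index",
                              exclude_specialist_only = TRUE)

write_results(list(genome_profiles = profiles,
                   feature_contrasts = contrasts,
                   unique_total_fits = fits,
                   slope_test = data.frame(slope_test),
                   per_phylum_redundancy = phylum),
              file.path("results", "03"))
message(sprintf("slopes %.3f (generalist) vs %.3f (specialist), p = %.3f",
                slope_test$slope_a, slope_test$slope_b, slope_test$p_value))
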