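#!/usr/bin/env Rscript
# Stage 6: pathway over-representation per module, hub-gene selection in the
# focal radiation-linked modules, the hub subnetwork, and the mapping of hub
# KOs onto genomes.

library(cryonet)

seed <- as.integer(Sys.getenv("CRYONET_SEED", "1"))
bundle <- readRDS(file.path("results", "bundle.rds"))
net <- readRDS(file.path("results", "network.rds"))
trait_corr <- readRDS(file.path("results", "trait_corr.rds"))
niche <- readRDS(file.path("results", "niche.rds"))
cfg <- run_config(rng_seed = seed)

universe <- rownames(net$clr)
rad <- bundle$meteo$radiation[match(colnames(net$clr),
                                    bundle$meteo$sample_id)]
ko_rad_r <- stats::setNames(as.numeric(stats::cor(t(net$clr), rad)),
                            universe)

enrich <- do.call(rbind, lapply(setdiff(unique(net$modules), "grey"),
  function(m) {
    e <- hypergeometric_enrichment(names(net$modules)[net$modules == m],
                                   bundle$pathways, universe)
    if (nrow(e) > 0) cbind(module = m, e) else NULL
  }))
hubs <- select_hub_genes(net$kme, net$modules, ko_rad_r, trait_corr,
                         bundle$pathways, universe,
                         whitelist = cfg$hub_pathways,
                         kme_threshold = cfg$kme_threshold,
                         trait_cor_threshold = cfg$trait_cor_threshold)
hub_net <- hub_subnetwork(hubs$ko_id, net$correlation, cfg$edge_threshold)
hub_map <- map_hubs_to_genomes(hubs$ko_id, bundle$annotations,
                               bundle$genomes)
sgb_clr <- clr_transform(czm_replace(bundle$sgb))
taxon_corr <- taxon_trait_spearman(
  sgb_clr, bundle$meteo$radiation[match(colnames(sgb_clr),
                                        bundle$meteo$sample_id)], niche)
hub_contrast <- hub_sensitivity_contrast(hub_map$counts, taxon_corr)

write_results(list(enrichment = enrich, hub_genes = hubs,
                   hub_edges = hub_net$edges,
                   hub_betweenness = data.frame(
                     ko = names(hub_net$betweenness),
                     betweenness = unname(hub_net$betweenness)),
                   hub_contrast = hub_contrast),
              file.path("results", "06"))
message(sprintf("%d hub genes (%s); %.0f%% of genomes carry a hub",
                nrow(hubs), paste(hubs$ko_id, collapse = ", "),
                100 * hub_map$fraction_with_hub))
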