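#' Run the full analysis pipeline
#'
#' Executes every stage in order — niche classification, genome features,
#' compositional transform, co-occurrence network, module selection,
#' enrichment and hub extraction, environmental association — on in-memory
#' inputs (e.g. a [simulate_bundle()]) or on files read with [read_table()].
#' All parameters and the seed are recorded in `run.log`; identical inputs,
#' config and seed reproduce identical outputs.
#'
#' @param inputs list with sgb, ko ([abundance_table()]s), meteo, samples,
#'   annotations, genomes, pathways data.frames.
#' @param config a [run_config()].
#' @param out_dir optional directory for TSV outputs and run.log.
#' @return list with every stage's results (invisible when writing).
#' @export
run_pipeline <- function(inputs, config = run_config(), out_dir = NULL) {
  required <- c("sgb", "ko", "meteo", "samples", "annotations", "genomes",
                "pathways")
  missing <- setdiff(required, names(inputs))
  assert_that(length(missing) == 0,
              sprintf("missing input(s): %s", paste(missing, collapse = ", ")))
  sgb_samples <- colnames(inputs$sgb)
  for (nm in c("ko")) {
    bad <- c(setdiff(sgb_samples, colnames(inputs[[nm]])),
             setdiff(colnames(inputs[[nm]]), sgb_samples))
    assert_that(length(bad) == 0,
                sprintf("sample ids differ between sgb and %s: %s", nm,
                        paste(bad, collapse = ", ")))
  }
  for (nm in c("meteo", "samples")) {
    bad <- c(setdiff(sgb_samples, inputs[[nm]]$sample_id),
             setdiff(inputs[[nm]]$sample_id, sgb_samples))
    assert_that(length(bad) == 0,
                sprintf("sample ids differ between sgb and %s: %s", nm,
                        paste(bad, collapse = ", ")))
  }
  meteo <- inputs$meteo[match(sgb_samples, inputs$meteo$sample_id), ]
  samples <- inputs$samples[match(sgb_samples, inputs$samples$sample_id), ]
  seed <- config$rng_seed
  log_lines <- c(sprintf("cryonet run, seed=%d", seed),
                 sprintf("config: %s", paste(names(config), vapply(
                   config, function(v) paste(format(v), collapse = ","),
                   character(1)), sep = "=", collapse = "; ")))

  # 1. niche classification
  niche <- classify_niche(inputs$sgb, config$n_permutations,
                          seed = derive_seed(seed, 11L),
                          method = config$null_model,
                          perm_depth = config$perm_depth,
                          ci_level = config$ci_level)
  log_lines <- c(log_lines, sprintf("niche: %d taxa classified (%s)",
                                    nrow(niche),
                                    paste(names(table(niche$class)),
                                          table(niche$class), collapse = ", ")))

  # 2. genome features
  profiles <- genome_profiles(inputs$annotations, inputs$genomes, niche)
  contrasts <- do.call(rbind, lapply(
    intersect(c("est_genome_size_bp", "gc_fraction", "redundancy_index"),
              names(profiles)),
    function(f) feature_contrast(profiles, f)))
  fits <- do.call(rbind, lapply(c("generalist", "specialist"), function(g) {
    if (sum(profiles$class == g) >= 3) unique_vs_total_fit(profiles, g)
  }))
  gen_pts <- profiles[profiles$class == "generalist",
                      c("n_total_ko", "n_unique_ko")]
  spe_pts <- profiles[profiles$class == "specialist",
                      c("n_total_ko", "n_unique_ko")]
  slope_test <- diffslope_test(gen_pts, spe_pts,
                               config$diffslope_permutations,
                               seed = derive_seed(seed, 12L))

  # 3-4. compositional transform + network on KOs
  net <- build_network(inputs$ko, config)
  trait_corr <- module_trait_correlation(net$eigengenes, meteo)

  # 5. module selection
  rad <- meteo$radiation
  cv <- cv_select_lambda(net$eigengenes, rad, config$k_folds,
                         seed = derive_seed(seed, 13L),
                         n_lambda = config$n_lambda,
                         lambda_min_ratio = config$lambda_min_ratio)
  final <- if (length(cv$selected) > 0) {
    standardized_final_model(net$eigengenes[, cv$selected, drop = FALSE], rad)
  } else NULL

  # 6. enrichment + hubs
  universe <- rownames(net$clr)
  ko_rad_r <- stats::setNames(
    as.numeric(stats::cor(t(net$clr), rad)), rownames(net$clr))
  enrich <- do.call(rbind, lapply(setdiff(unique(net$modules), "grey"),
    function(m) {
      e <- hypergeometric_enrichment(names(net$modules)[net$modules == m],
                                     inputs$pathways, universe)
      if (nrow(e) > 0) cbind(module = m, e) else NULL
    }))
  hubs <- select_hub_genes(net$kme, net$modules, ko_rad_r, trait_corr,
                           inputs$pathways, universe,
                           whitelist = config$hub_pathways,
                           kme_threshold = config$kme_threshold,
                           trait_cor_threshold = config$trait_cor_threshold)
  hub_net <- if (nrow(hubs) >= 2) {
    hub_subnetwork(hubs$ko_id, net$correlation, config$edge_threshold)
  } else NULL
  hub_map <- map_hubs_to_genomes(hubs$ko_id, inputs$annotations,
                                 inputs$genomes)

  # 7. environment association
  sgb_clr <- clr_transform(czm_replace(inputs$sgb))
  covs <- meteo[, c("radiation", "temperature", "windspeed",
                    "precipitation", "evaporation")]
  vf <- vif_filter(covs, config$vif_threshold)
  covs_kept <- covs[, vf$retained, drop = FALSE]
  rda <- rda_fit(sgb_clr, covs_kept, config$envfit_permutations,
                 seed = derive_seed(seed, 14L))
  partition <- hierarchical_partition(sgb_clr, covs_kept)
  comm_dist <- stats::dist(t(sgb_clr))          # Aitchison distance
  cov_dists <- lapply(covs_kept, stats::dist)
  mrm_res <- mrm(comm_dist, cov_dists, config$mrm_permutations,
                 seed = derive_seed(seed, 15L))
  taxon_corr <- taxon_trait_spearman(sgb_clr, rad, niche)
  class_fits <- class_aggregate_fit(inputs$sgb, niche, rad)
  decay <- distance_decay(comm_dist, rad, samples$latitude,
                          samples$longitude)
  hub_contrast <- if (nrow(hubs) > 0 &&
                      length(unique(hub_map$counts > 0)) == 2) {
    hub_sensitivity_contrast(hub_map$counts, taxon_corr)
  } else NULL

  results <- list(
    niche = niche, profiles = profiles, feature_contrasts = contrasts,
    unique_total_fits = fits, slope_test = slope_test,
    network = net, module_trait_corr = trait_corr,
    lasso = cv, final_model = final,
    enrichment = enrich, hubs = hubs, hub_network = hub_net,
    hub_map = hub_map, hub_contrast = hub_contrast,
    vif = vf, rda = rda, partition = partition, mrm = mrm_res,
    taxon_trait_corr = taxon_corr, class_fits = class_fits,
    distance_decay = decay, config = config
  )

  if (!is.null(out_dir)) {
    tabs <- list(
      niche_classification = niche,
      genome_profiles = profiles,
      feature_contrasts = contrasts,
      slope_tests = data.frame(slope_test),
      module_assignments = data.frame(ko = names(net$modules),
                                      module = unname(net$modules)),
      eigengenes = t(net$eigengenes),
      soft_threshold_fit = net$fit_table,
      module_trait_corr = trait_corr,
      cv_table = cv$cv_table,
      vif = data.frame(covariate = names(vf$vif), vif = unname(vf$vif)),
      rda_summary = data.frame(explained_fraction = rda$explained_fraction,
                               F = rda$F, p = rda$p_value),
      envfit = rda$envfit_table,
      partition_table = partition,
      mrm = mrm_res$coefficients,
      taxon_trait_corr = taxon_corr,
      class_fits = class_fits,
      distance_decay = decay
    )
    if (!is.null(fits)) tabs$unique_total_fits <- fits
    if (!is.null(final)) tabs$final_model <- final$coefficients
    if (!is.null(enrich)) tabs$enrichment <- enrich
    if (nrow(hubs) > 0) tabs$hub_genes <- hubs
    if (!is.null(hub_net) && nrow(hub_net$edges) > 0)
      tabs$hub_edges <- hub_net$edges
    if (!is.null(hub_contrast)) tabs$hub_contrast <- hub_contrast
    write_results(tabs, out_dir)
    writeLines(c(log_lines, "stages complete"),
               file.path(out_dir, "run.log"))
    return(invisible(results))
  }
  results
}
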