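#' Simulation specification
#'
#' Defaults define the study conditions every planted-structure test runs
#' under: a 60-sample radiation gradient; taxa split 15/66/39 into planted
#' generalists (full occupancy, low mean abundance, abundance declining with
#' radiation), specialists (5% occupancy inside taxon-specific radiation
#' niche windows, higher abundance, increasing with radiation) and
#' intermediates (occupancy near the table's overall fill, so
#' they sit inside the fixed-margin null interval); 1000 KOs with four correlated blocks of
#' which three carry a radiation-linked latent factor (target correlations
#' +0.83, -0.77, +0.45 — chosen so the three linked eigengenes jointly
#' explain about 78.5% of radiation variance); class-dependent gene
#' duplication (extra copies per gene: 0.1 generalist, 0.3 specialist) and
#' genome size/GC normals (4.58/4.20 Mbp, GC 0.61/0.53); five planted hub
#' KOs tied to both their block factor and radiation, carried by 54% of
#' genomes.
#'
#' @param ... overrides for any default field.
#' @return A validated `sim_spec` list.
#' @export
sim_spec <- function(...) {
  spec <- list(
    n_samples = 60L,
    n_generalists = 15L,
    n_specialists = 66L,
    n_uncategorized = 39L,
    # community layer
    mean_abundance = c(generalist = 10, specialist = 80, uncategorized = 30),
    occupancy = c(generalist = 1.0, specialist = 0.05, uncategorized = 0.22),
    slope = c(generalist = -0.7, specialist = 0.4, uncategorized = 0),
    # negative-binomial dispersion (size); intermediates are overdispersed so
    # their breadth sits inside the null interval rather than at its edge
    nb_size = c(generalist = 10, specialist = 10, uncategorized = 3),
    # geometric decay of expected abundance with rank distance from the
    # niche optimum (1 = flat window); concentration pushes specialist
    # breadth well below the null interval
    window_concentration = c(generalist = 1, specialist = 0.3,
                             uncategorized = 1),
    # meteorology
    radiation_range = c(300, 900),   # MJ/m^2
    radiation_jitter = 10,
    meteo_cor = 0.3,
    # KO layer
    n_ko = 1000L,
    n_modules = 4L,
    # sizes chosen so sum(size * link) ~ 0: under TPM closure the CLR
    # log-mean then carries no net radiation component, keeping unlinked
    # KOs trait-neutral and linked eigengenes at their target correlations
    module_sizes = c(70L, 108L, 55L, 50L),
    trait_link = c(0.83, -0.77, 0.45, 0),  # per-module radiation correlation
    within_module_cor = 0.7,
    noise_sd = 0.7,                  # log-scale SD of KO abundances
    hub_kos_per_module = c(3L, 2L, 0L, 0L),
    hub_kme_target = 0.95,
    hub_trait_target = 0.90,
    # genome layer
    duplication_rate = c(generalist = 0.1, specialist = 0.3,
                         uncategorized = 0.2),
    genome_size_mean = c(generalist = 4.58e6, specialist = 4.20e6,
                         uncategorized = 4.39e6),
    genome_size_sd = c(generalist = 1.56e6, specialist = 1.50e6,
                       uncategorized = 1.53e6),
    gc_mean = c(generalist = 0.61, specialist = 0.53, uncategorized = 0.57),
    gc_sd = c(generalist = 0.08, specialist = 0.11, uncategorized = 0.10),
    mean_kos_per_genome = 300,
    hub_fraction = 0.54,
    # pathway layer
    n_pathways = 12L,
    biofilm_pathway = "biofilm formation",
    biofilm_extra_per_module = 8L,
    # one extra whitelisted pathway per additional hub-bearing module, so
    # every focal module has an enriched whitelisted pathway of its own
    secondary_hub_pathways = c("flagellar assembly", "quorum sensing",
                               "secretion system"),
    rng_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(spec))
  assert_that(length(unknown) == 0,
              sprintf("unknown sim_spec field(s): %s",
                      paste(unknown, collapse = ", ")))
  spec[names(over)] <- over
  assert_that(spec$n_samples >= 4, "need at least 4 samples")
  assert_that(sum(spec$module_sizes) <= spec$n_ko,
              "module sizes exceed the KO universe")
  assert_that(length(spec$module_sizes) == spec$n_modules &&
              length(spec$trait_link) == spec$n_modules,
              "module_sizes and trait_link must have n_modules entries")
  assert_that(spec$within_module_cor > 0 && spec$within_module_cor < 1,
              "within_module_cor must lie in (0,1)")
  assert_that(all(spec$duplication_rate >= 0), "duplication rates must be >= 0")
  occ_ok <- vapply(spec$occupancy, function(o) {
    (is.integer(o) && o >= 1L) || (is.numeric(o) && o > 0 && o <= 1)
  }, logical(1))
  assert_that(all(occ_ok),
              "occupancy must be a double fraction in (0,1] or an integer sample count")
  structure(spec, class = "sim_spec")
}

#' Simulate per-sample meteorological covariates
#'
#' Radiation is an evenly spaced gradient over `radiation_range` plus
#' Gaussian jitter; the other four covariates are drawn with pairwise
#' correlation `meteo_cor` to standardized radiation. Also returns sample
#' metadata (site, region, coordinates): regions (ALP, ARC, TP) are drawn
#' with radiation-dependent log-odds so they associate with the gradient
#' (ALP low, TP high) while their radiation ranges overlap, mirroring
#' hemispheric survey structure.
#'
#' @param spec a [sim_spec()].
#' @return list with `meteo` (sample_id, radiation, temperature, windspeed,
#'   precipitation, evaporation) and `samples` (sample_id, site, region,
#'   latitude, longitude) data.frames.
#' @export
simulate_meteo <- function(spec) {
  set.seed(derive_seed(spec$rng_seed, 1L))
  n <- spec$n_samples
  sample_id <- sprintf("S%03d", seq_len(n))
  rad <- seq(spec$radiation_range[1], spec$radiation_range[2], length.out = n) +
    stats::rnorm(n, 0, spec$radiation_jitter)
  rad <- pmax(rad, 0)
  s <- zscore(rad)
  draw <- function(mu, sigma) {
    mu + sigma * (spec$meteo_cor * s +
                  sqrt(1 - spec$meteo_cor^2) * stats::rnorm(n))
  }
  meteo <- data.frame(
    sample_id = sample_id,
    radiation = rad,
    temperature = draw(266, 6),
    windspeed = pmax(draw(4, 1.5), 0),
    precipitation = pmax(draw(0.08, 0.04), 0),
    evaporation = draw(-0.005, 0.002),
    stringsAsFactors = FALSE
  )
  # regions are associated with, but not nested in, the gradient: assignment
  # is probabilistic with radiation-dependent log-odds, so their radiation
  # ranges overlap and geographic distance only coarsely tracks radiation
  logits <- cbind(ALP = log(0.10) - 1.5 * s,
                  ARC = log(0.45),
                  TP = log(0.45) + 1.5 * s)
  w <- exp(logits) / rowSums(exp(logits))
  region <- vapply(seq_len(n), function(i) {
    sample(colnames(w), 1, prob = w[i, ])
  }, character(1))
  base_lat <- c(ALP = 46.5, ARC = 74, TP = 32)
  base_lon <- c(ALP = 10.5, ARC = -30, TP = 86)
  within <- stats::ave(seq_len(n), region, FUN = seq_along)
  samples <- data.frame(
    sample_id = sample_id,
    site = paste0(region, "_site", ceiling(within / 3)),
    region = region,
    latitude = pmin(90, pmax(-90, base_lat[region] + stats::rnorm(n, 0, 2))),
    longitude = base_lon[region] + stats::rnorm(n, 0, 6),
    stringsAsFactors = FALSE
  )
  rownames(samples) <- NULL
  list(meteo = meteo, samples = samples)
}

# number of occupied samples implied by an occupancy parameter:
# integer-typed values are sample counts, double-typed values are fractions
# of the sample set (1.0 = present everywhere)
occupancy_count <- function(occ, n_samples) {
  if (is.integer(occ)) as.integer(min(occ, n_samples))
  else max(1L, as.integer(round(occ * n_samples)))
}

#' Simulate the SGB community table with planted niche classes
#'
#' Generalists are present in every sample at low, near-uniform expected
#' abundance that declines multiplicatively with standardized radiation;
#' specialists are present in a small subset of samples (default 5%
#' occupancy) at higher abundance increasing with radiation; intermediates
#' occupy roughly the table's fill fraction with no trend. Occupancy values
#' are fractions when double-typed and sample counts when integer-typed
#' (so `occupancy = c(specialist = 1L, ...)` plants single-sample
#' specialists). Every partial-occupancy taxon draws a radiation optimum
#' uniformly over the observed gradient and occupies the samples nearest
#' that optimum (a niche window), so community composition turns over along
#' the radiation gradient; the niche-breadth truth is unchanged because
#' Levins' B and the fixed-margin null depend only on the abundance values
#' and the table margins, not on which samples are occupied.
#' Counts are drawn from a
#' negative binomial around the expectations and scaled per sample to TPM
#' (columns sum to 1e6).
#'
#' @param spec a [sim_spec()].
#' @param meteo the `meteo` data.frame from [simulate_meteo()].
#' @return list with `table` (an [abundance_table()]) and `truth`
#'   (taxon_id, class, occupancy_n).
#' @export
simulate_community <- function(spec, meteo) {
  assert_that(spec$n_generalists >= 1 && spec$n_specialists >= 1 &&
              spec$n_uncategorized >= 1, "each class needs at least one taxon")
  set.seed(derive_seed(spec$rng_seed, 2L))
  n <- spec$n_samples
  s <- zscore(meteo$radiation)
  classes <- rep(c("generalist", "specialist", "uncategorized"),
                 c(spec$n_generalists, spec$n_specialists, spec$n_uncategorized))
  n_taxa <- length(classes)
  taxon_id <- sprintf("SGB%04d", seq_len(n_taxa))
  counts <- matrix(0, n_taxa, n, dimnames = list(taxon_id, meteo$sample_id))
  occ_n <- integer(n_taxa)
  nb_size <- rep_len(unlist(spec$nb_size), 3)
  names(nb_size) <- c("generalist", "specialist", "uncategorized")
  conc <- rep_len(unlist(spec$window_concentration), 3)
  names(conc) <- c("generalist", "specialist", "uncategorized")
  for (i in seq_len(n_taxa)) {
    cl <- classes[i]
    lambda <- spec$mean_abundance[[cl]] * exp(spec$slope[[cl]] * s)
    k <- occupancy_count(spec$occupancy[[cl]], n)
    occ_n[i] <- k
    if (k >= n) {
      present <- seq_len(n)
      w <- rep(1, n)
    } else {
      # niche window: occupy the k samples nearest a random radiation
      # optimum, so composition turns over along the gradient; expected
      # abundance decays geometrically with rank distance from the optimum
      opt <- stats::runif(1, min(meteo$radiation), max(meteo$radiation))
      idx <- order(abs(meteo$radiation - opt))[seq_len(k)]
      w <- conc[[cl]]^(seq_len(k) - 1)
      w <- w / mean(w)
      o <- order(idx)
      present <- idx[o]
      w <- w[o]
    }
    mu <- lambda[present] * w
    counts[i, present] <- stats::rnbinom(length(present), mu = mu,
                                         size = nb_size[[cl]])
    # a planted taxon must remain observable: re-seed one occupied cell if
    # sampling zeroed the whole row
    if (all(counts[i, ] == 0)) counts[i, present[1]] <- 1
  }
  tpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  list(table = abundance_table(tpm),
       truth = data.frame(taxon_id = taxon_id, class = classes,
                          occupancy_n = occ_n, stringsAsFactors = FALSE))
}

# coefficients (u, v, w) putting a hub KO at target correlations with its
# module factor and with radiation, given the factor-radiation link a
hub_coefficients <- function(a, kme_target, trait_target) {
  a <- abs(a)
  det <- 1 - a^2
  u <- (kme_target - a * trait_target) / det
  v <- (trait_target - a * kme_target) / det
  w2 <- 1 - (u^2 + v^2 + 2 * u * v * a)
  assert_that(w2 >= 0,
              "hub targets are infeasible for this module-radiation link")
  c(u = u, v = v, w = sqrt(w2))
}

#' Simulate the KO abundance table with planted correlated blocks
#'
#' Each module shares a latent factor; KOs load on it with
#' `sqrt(within_module_cor)` on the log scale so CLR-scale correlations
#' within a block approximate `within_module_cor`. Trait-linked modules'
#' factors equal `trait_link * z(radiation)` plus orthogonal noise. Planted
#' hub KOs combine their module factor and radiation directly so that both
#' their module membership and their radiation correlation reach the
#' configured targets. Log abundances are exponentiated and scaled per
#' sample to TPM.
#'
#' @param spec a [sim_spec()].
#' @param meteo the `meteo` data.frame from [simulate_meteo()].
#' @return list with `table` ([abundance_table()]), `truth` (ko_id, module:
#'   integer, 0 = background, is_hub), and `factors` (n_samples x n_modules
#'   latent factor matrix).
#' @export
simulate_ko_matrix <- function(spec, meteo) {
  assert_that(spec$n_modules >= 2, "need at least two modules")
  assert_that(any(spec$trait_link > 0) && any(spec$trait_link < 0),
              "need at least one positively and one negatively linked module")
  set.seed(derive_seed(spec$rng_seed, 3L))
  n <- spec$n_samples
  s <- zscore(meteo$radiation)
  m <- spec$n_modules
  if (any(spec$module_sizes < 10))
    warning("some planted modules are small and may be hard to detect")
  # module-specific noise directions are Gram-Schmidt orthogonalized
  # against radiation and against each other, so in-sample factor
  # correlations equal exactly trait_link[i] * trait_link[j]
  factors <- matrix(NA_real_, n, m)
  basis <- matrix(s, n, 1)
  for (j in seq_len(m)) {
    a <- spec$trait_link[j]
    eta <- stats::rnorm(n)
    eta <- zscore(stats::residuals(stats::lm(eta ~ basis)))
    basis <- cbind(basis, eta)
    factors[, j] <- a * s + sqrt(1 - a^2) * eta
  }
  module_of <- rep(0L, spec$n_ko)
  idx <- 1L
  for (j in seq_len(m)) {
    module_of[idx:(idx + spec$module_sizes[j] - 1L)] <- j
    idx <- idx + spec$module_sizes[j]
  }
  ko_id <- sprintf("K%05d", seq_len(spec$n_ko))
  is_hub <- rep(FALSE, spec$n_ko)
  rho <- spec$within_module_cor
  logx <- matrix(NA_real_, spec$n_ko, n, dimnames = list(ko_id, meteo$sample_id))
  base <- stats::rnorm(spec$n_ko, 4, 1)   # log-scale baseline abundance
  for (i in seq_len(spec$n_ko)) {
    mod <- module_of[i]
    y <- if (mod == 0) stats::rnorm(n) else
      sqrt(rho) * factors[, mod] + sqrt(1 - rho) * stats::rnorm(n)
    logx[i, ] <- base[i] + spec$noise_sd * y
  }
  # plant hub KOs at the head of each linked module
  for (j in seq_len(m)) {
    nh <- spec$hub_kos_per_module[j]
    if (nh == 0) next
    cf <- hub_coefficients(spec$trait_link[j], spec$hub_kme_target,
                           spec$hub_trait_target)
    sgn <- sign(spec$trait_link[j])
    members <- which(module_of == j)
    for (h in members[seq_len(nh)]) {
      y <- cf["u"] * factors[, j] + cf["v"] * sgn * s +
        cf["w"] * stats::rnorm(n)
      logx[h, ] <- base[h] + spec$noise_sd * y
      is_hub[h] <- TRUE
    }
  }
  x <- exp(logx)
  tpm <- sweep(x, 2, colSums(x), "/") * 1e6
  list(table = abundance_table(tpm),
       truth = data.frame(ko_id = ko_id, module = module_of, is_hub = is_hub,
                          stringsAsFactors = FALSE),
       factors = factors)
}

#' Simulate per-genome KO annotations and genome metadata
#'
#' Each genome draws a KO repertoire from the KO universe, with repertoire
#' size proportional to genome size (`mean_kos_per_genome` at the average
#' planted genome size); every gene gains extra copies at a class-specific
#' Poisson rate (`duplication_rate` = expected extra copies per gene), so
#' the expected gene redundancy index is `1 / (1 + rate)`. Genome size and
#' GC come from class-specific normals. A `hub_fraction` of genomes carries
#' one or more planted hub KOs.
#'
#' @param spec a [sim_spec()].
#' @param classes data.frame with `taxon_id`, `class` (the community truth).
#' @param hub_kos character vector of planted hub KO ids.
#' @return list with `annotations` (genome_id, ko_id, copy_count),
#'   `genomes` (metadata incl. taxonomy) and `truth` (genome_id, carries_hub).
#' @export
simulate_genomes <- function(spec, classes, hub_kos = character(0)) {
  assert_that(all(classes$class %in% names(spec$duplication_rate)),
              "classes must cover all simulated taxa")
  set.seed(derive_seed(spec$rng_seed, 4L))
  ko_universe <- sprintf("K%05d", seq_len(spec$n_ko))
  non_hub_universe <- setdiff(ko_universe, hub_kos)
  phyla <- c("Proteobacteria", "Bacteroidota", "Actinobacteriota",
             "Armatimonadota", "Patescibacteria", "Cyanobacteria")
  ann <- vector("list", nrow(classes))
  carries <- rep(FALSE, nrow(classes))
  genomes <- data.frame(
    genome_id = classes$taxon_id,
    est_genome_size_bp = NA_real_, gc_fraction = NA_real_,
    completeness_pct = NA_real_, contamination_pct = NA_real_,
    taxonomy = NA_character_, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(classes))) {
    cl <- classes$class[i]
    genomes$est_genome_size_bp[i] <-
      max(5e5, stats::rnorm(1, spec$genome_size_mean[[cl]],
                            spec$genome_size_sd[[cl]]))
    genomes$gc_fraction[i] <-
      min(0.8, max(0.2, stats::rnorm(1, spec$gc_mean[[cl]], spec$gc_sd[[cl]])))
    genomes$completeness_pct[i] <- stats::runif(1, 50, 100)
    genomes$contamination_pct[i] <- stats::runif(1, 0, 10)
    phy <- sample(phyla, 1)
    genomes$taxonomy[i] <- sprintf("d__Bacteria;p__%s;c__;o__;f__;g__%s;s__",
                                   phy, paste0(phy, "_g", sample.int(30, 1)))
    # repertoire size scales with genome size (mean_kos_per_genome at the
    # class-average size), so larger genomes span a wide total-KO range
    n_ko_i <- round(spec$mean_kos_per_genome *
                      genomes$est_genome_size_bp[i] /
                      mean(spec$genome_size_mean) + stats::rnorm(1, 0, 10))
    n_ko_i <- min(length(non_hub_universe), max(30L, n_ko_i))
    kos <- sample(non_hub_universe, n_ko_i)
    if (length(hub_kos) > 0 && stats::runif(1) < spec$hub_fraction) {
      kos <- c(kos, sample(hub_kos, sample.int(length(hub_kos), 1)))
      carries[i] <- TRUE
    }
    copies <- 1L + stats::rpois(length(kos), spec$duplication_rate[[cl]])
    ann[[i]] <- data.frame(genome_id = classes$taxon_id[i], ko_id = kos,
                           copy_count = copies, stringsAsFactors = FALSE)
  }
  list(annotations = do.call(rbind, ann), genomes = genomes,
       truth = data.frame(genome_id = classes$taxon_id, carries_hub = carries,
                          stringsAsFactors = FALSE))
}

#' Simulate a KO-to-pathway map
#'
#' Every KO is assigned 1-3 generic pathway labels. All planted hub KOs,
#' plus a few extra members of the first hub-bearing module, are
#' additionally assigned the designated biofilm-formation pathway; every
#' further hub-bearing module gets its own secondary whitelisted pathway
#' (its hubs plus a few extra members), so each focal module carries an
#' enriched whitelisted pathway and hub selection is recoverable.
#'
#' @param spec a [sim_spec()].
#' @param ko_truth the `truth` table from [simulate_ko_matrix()].
#' @return data.frame with ko_id, pathway_id, pathway_name.
#' @export
simulate_pathway_map <- function(spec, ko_truth) {
  assert_that(spec$n_ko >= spec$n_pathways,
              "need at least as many KOs as pathways")
  set.seed(derive_seed(spec$rng_seed, 5L))
  generic <- sprintf("pathway_%02d", seq_len(spec$n_pathways))
  rows <- lapply(seq_len(nrow(ko_truth)), function(i) {
    k <- sample.int(3, 1)
    data.frame(ko_id = ko_truth$ko_id[i],
               pathway_id = sample(generic, k), stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  map$pathway_name <- map$pathway_id
  hub_modules <- sort(unique(ko_truth$module[ko_truth$is_hub]))
  assert_that(length(hub_modules) <= length(spec$secondary_hub_pathways) + 1,
              "not enough secondary hub pathways for the hub-bearing modules")
  planted <- list()
  if (length(hub_modules) > 0) {
    first_members <- ko_truth$ko_id[ko_truth$module == hub_modules[1] &
                                    !ko_truth$is_hub]
    planted[[spec$biofilm_pathway]] <-
      c(ko_truth$ko_id[ko_truth$is_hub],
        utils::head(first_members, spec$biofilm_extra_per_module))
    for (i in seq_along(hub_modules)[-1]) {
      j <- hub_modules[i]
      members <- ko_truth$ko_id[ko_truth$module == j & !ko_truth$is_hub]
      planted[[spec$secondary_hub_pathways[i - 1L]]] <-
        c(ko_truth$ko_id[ko_truth$is_hub & ko_truth$module == j],
          utils::head(members, spec$biofilm_extra_per_module))
    }
  }
  for (i in seq_along(planted)) {
    map <- rbind(map, data.frame(ko_id = planted[[i]],
                                 pathway_id = sprintf("map_hub_%02d", i),
                                 pathway_name = names(planted)[i],
                                 stringsAsFactors = FALSE))
  }
  rownames(map) <- NULL
  map
}

#' Generate the full synthetic input bundle
#'
#' Runs every generator under one seed and returns (optionally writes) the
#' complete set of pipeline inputs plus ground-truth sidecar tables for
#' recovery tests.
#'
#' @param spec a [sim_spec()].
#' @param out_dir optional directory; when given, all tables are written as
#'   TSV via [write_results()].
#' @return list with sgb, ko (abundance tables), meteo, samples, annotations,
#'   genomes, pathways, and truth_* sidecars.
#' @export
simulate_bundle <- function(spec = sim_spec(), out_dir = NULL) {
  met <- simulate_meteo(spec)
  comm <- simulate_community(spec, met$meteo)
  kom <- simulate_ko_matrix(spec, met$meteo)
  hub_kos <- kom$truth$ko_id[kom$truth$is_hub]
  gen <- simulate_genomes(spec, comm$truth, hub_kos)
  pathways <- simulate_pathway_map(spec, kom$truth)
  bundle <- list(sgb = comm$table, ko = kom$table, meteo = met$meteo,
                 samples = met$samples, annotations = gen$annotations,
                 genomes = gen$genomes, pathways = pathways,
                 truth_classes = comm$truth, truth_modules = kom$truth,
                 truth_hub_carriage = gen$truth, factors = kom$factors)
  if (!is.null(out_dir)) {
    tabs <- list(
      sgb_abundance = data.frame(taxon_id = rownames(comm$table),
                                 unclass(comm$table), check.names = FALSE),
      ko_abundance = data.frame(ko_id = rownames(kom$table),
                                unclass(kom$table), check.names = FALSE),
      meteo = met$meteo, samples = met$samples,
      annotations = gen$annotations, genomes = gen$genomes,
      pathways = pathways,
      truth_classes = comm$truth, truth_modules = kom$truth,
      truth_hub_carriage = gen$truth
    )
    write_results(tabs, out_dir)
  }
  bundle
}
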