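test_that("sim_spec validates fields and occupancy typing", {
  expect_s3_class(sim_spec(), "sim_spec")
  expect_error(sim_spec(bogus = 1), "unknown sim_spec field")
  expect_error(sim_spec(module_sizes = c(900L, 108L, 55L, 50L)),
               "exceed the KO universe")
  expect_error(sim_spec(trait_link = c(0.5, 0.2)), "n_modules entries")
  expect_error(sim_spec(occupancy = c(generalist = 0, specialist = 0.05,
                                      uncategorized = 0.22)), "occupancy")
  # integer-typed occupancy = sample count; double-typed = fraction
  expect_identical(cryonet:::occupancy_count(1L, 60), 1L)
  expect_identical(cryonet:::occupancy_count(1.0, 60), 60L)
  expect_identical(cryonet:::occupancy_count(0.05, 60), 3L)
})

test_that("simulated community matches the planted design", {
  spec <- sim_spec()
  met <- simulate_meteo(spec)
  comm <- simulate_community(spec, met$meteo)
  tab <- unclass(comm$table)
  expect_identical(dim(tab), c(120L, 60L))
  expect_equal(unname(colSums(tab)), rep(1e6, 60))        # TPM closure
  occ <- rowSums(tab > 0)
  truth <- comm$truth
  # generalists are designed into every sample; negative-binomial sampling
  # can zero a handful of low-expectation cells at the gradient extremes
  expect_true(all(truth$occupancy_n[truth$class == "generalist"] == 60L))
  expect_true(mean(occ[truth$class == "generalist"]) > 55)
  expect_true(all(occ[truth$class == "specialist"] <= 3))
  # specialists occupy contiguous radiation windows
  rad_rank <- rank(met$meteo$radiation)
  spec_rows <- which(truth$class == "specialist" & occ == 3)
  spans <- vapply(spec_rows, function(i) {
    r <- sort(rad_rank[tab[i, ] > 0])
    r[length(r)] - r[1]
  }, numeric(1))
  expect_true(median(spans) <= 4)
})

test_that("planted KO factors are exactly orthogonalized", {
  spec <- sim_spec()
  met <- simulate_meteo(spec)
  kom <- simulate_ko_matrix(spec, met$meteo)
  s <- cryonet:::zscore(met$meteo$radiation)
  f <- kom$factors
  for (j in 1:4) {
    expect_equal(cor(f[, j], s), spec$trait_link[j], tolerance = 1e-10)
  }
  # pairwise factor correlations equal the product of the radiation links
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(cor(f[, i], f[, j]),
                 spec$trait_link[i] * spec$trait_link[j], tolerance = 1e-10)
  }
  expect_identical(sum(kom$truth$is_hub), 5L)
  expect_identical(as.integer(table(kom$truth$module)[-1]),
                   spec$module_sizes)
})

test_that("planted hubs reach their kME and radiation targets in CLR space", {
  spec <- sim_spec()
  met <- simulate_meteo(spec)
  kom <- simulate_ko_matrix(spec, met$meteo)
  clr <- clr_transform(unclass(kom$table))
  s <- met$meteo$radiation
  hubs <- kom$truth$ko_id[kom$truth$is_hub]
  r_rad <- abs(cor(t(clr[hubs, ]), s))
  expect_true(all(r_rad > 0.8))
})

test_that("genome repertoire size scales with genome size", {
  spec <- sim_spec()
  met <- simulate_meteo(spec)
  comm <- simulate_community(spec, met$meteo)
  kom <- simulate_ko_matrix(spec, met$meteo)
  gen <- simulate_genomes(spec, comm$truth,
                          kom$truth$ko_id[kom$truth$is_hub])
  prof <- suppressWarnings(genome_profiles(gen$annotations, gen$genomes))
  expect_true(cor(prof$est_genome_size_bp, prof$n_unique_ko) > 0.9)
  expect_true(all(table(gen$annotations$genome_id) >= 30))
  expect_true(all(gen$annotations$copy_count >= 1))
})

test_that("pathway map plants recoverable hub pathways", {
  spec <- sim_spec()
  met <- simulate_meteo(spec)
  kom <- simulate_ko_matrix(spec, met$meteo)
  pm <- simulate_pathway_map(spec, kom$truth)
  hubs <- kom$truth$ko_id[kom$truth$is_hub]
  biofilm <- unique(pm$ko_id[pm$pathway_name == spec$biofilm_pathway])
  expect_true(all(hubs %in% biofilm))        # spec post-condition
  # each hub-bearing module has a whitelisted pathway concentrated in it
  flag <- unique(pm$ko_id[pm$pathway_name == "flagellar assembly"])
  mod_of_flag <- kom$truth$module[match(flag, kom$truth$ko_id)]
  expect_true(all(mod_of_flag == 2))
  expect_true(all(pm$ko_id %in% kom$truth$ko_id))
})

test_that("the full bundle is deterministic given the seed", {
  b1 <- simulate_bundle(sim_spec(rng_seed = 9L))
  b2 <- simulate_bundle(sim_spec(rng_seed = 9L))
  expect_identical(b1$sgb, b2$sgb)
  expect_identical(b1$ko, b2$ko)
  expect_identical(b1$annotations, b2$annotations)
  expect_identical(b1$samples, b2$samples)
  b3 <- simulate_bundle(sim_spec(rng_seed = 10L))
  expect_false(identical(unclass(b1$sgb), unclass(b3$sgb)))
})
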