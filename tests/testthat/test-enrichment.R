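test_that("hypergeometric enrichment closed form and BH adjustment", {
  universe <- sprintf("K%02d", 1:10)
  pm <- data.frame(ko_id = universe[1:5], pathway_id = "map01",
                   pathway_name = "biofilm formation")
  module <- universe[c(1, 2, 3, 4)]          # k = 4 of K = 5, n = 4, N = 10
  enr <- hypergeometric_enrichment(module, pm, universe)
  expect_equal(enr$p_value, 5 / 210)          # C(5,4) C(5,0) / C(10,4)
  expect_identical(c(enr$k, enr$K, enr$n, enr$N), c(4L, 5L, 4L, 10L))
  # BH on (0.01, 0.02, 0.04) gives (0.03, 0.03, 0.04)
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
  expect_error(hypergeometric_enrichment("K99", pm, universe), "subset")
})

test_that("enrichment p-values match the summation oracle", {
  set.seed(19)
  universe <- sprintf("K%02d", 1:12)
  pm <- data.frame(
    ko_id = c(sample(universe, 5), sample(universe, 4)),
    pathway_id = rep(c("map01", "map02"), c(5, 4)),
    pathway_name = rep(c("a", "b"), c(5, 4)))
  module <- sample(universe, 6)
  enr <- hypergeometric_enrichment(module, pm, universe)
  for (i in seq_len(nrow(enr))) {
    expect_equal(enr$p_value[i],
                 enum_hypergeom(enr$k[i], enr$K[i], 12, 6), tolerance = 1e-12)
  }
})

test_that("betweenness closed form and brute-force equivalence", {
  # path graph a - b - c: only the middle node lies on a shortest path
  r <- diag(3); r[1, 2] <- r[2, 1] <- 0.9; r[2, 3] <- r[3, 2] <- 0.8
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  net <- hub_subnetwork(c("a", "b", "c"), r, edge_threshold = 0.6)
  expect_equal(unname(net$betweenness), c(0, 1, 0))
  expect_identical(nrow(net$edges), 2L)
  set.seed(20)
  n <- 7
  adj <- matrix(rbinom(n * n, 1, 0.4), n); adj <- adj * t(adj); diag(adj) <- 0
  rr <- adj * 0.9; diag(rr) <- 1
  ids <- letters[1:n]; dimnames(rr) <- list(ids, ids)
  net2 <- suppressWarnings(hub_subnetwork(ids, rr, edge_threshold = 0.6))
  expect_equal(unname(net2$betweenness), brute_betweenness(adj),
               tolerance = 1e-10)
})

test_that("select_hub_genes applies all three gates", {
  # focal modules: blue (positive) and brown (negative); turquoise ignored
  trait_corr <- data.frame(
    module = c("blue", "brown", "turquoise"),
    covariate = "radiation",
    pearson_r = c(0.9, -0.85, 0.3), p_value = 0.001)
  kos <- sprintf("K%02d", 1:30)
  module_of <- stats::setNames(rep(c("blue", "brown", "turquoise"), each = 10),
                               kos)
  kme <- matrix(0.2, 30, 3, dimnames = list(kos, c("blue", "brown",
                                                   "turquoise")))
  kme[1:10, "blue"] <- c(0.95, 0.95, 0.95, rep(0.85, 7))   # K01-03 pass kME
  kme[11:20, "brown"] <- 0.95
  trait_r <- stats::setNames(rep(0.1, 30), kos)
  trait_r[c("K01", "K02")] <- 0.9       # only K01, K02 pass |r| > 0.8
  trait_r[11:20] <- -0.85               # all brown members pass
  universe <- kos
  pm <- data.frame(ko_id = c(kos[1:8], kos[25:30]),
                   pathway_id = rep(c("map1", "map2"), c(8, 6)),
                   pathway_name = rep(c("biofilm formation", "unlisted"),
                                      c(8, 6)))
  hubs <- select_hub_genes(kme, module_of, trait_r, trait_corr, pm, universe,
                           whitelist = "biofilm formation")
  # blue: K01, K02 pass kME + trait + annotated to the enriched whitelisted
  # pathway; brown has no enriched whitelisted pathway at all
  expect_identical(sort(hubs$ko_id), c("K01", "K02"))
  expect_identical(unique(hubs$module), "blue")
  expect_identical(unique(hubs$pathways), "biofilm formation")
  none <- select_hub_genes(kme, module_of, trait_r, trait_corr, pm, universe,
                           whitelist = "nothing")
  expect_identical(nrow(none), 0L)
})

test_that("map_hubs_to_genomes tallies presence and phyla", {
  ann <- data.frame(genome_id = c("g1", "g1", "g2", "g3"),
                    ko_id = c("K1", "K2", "K1", "K9"),
                    copy_count = 1L)
  out <- map_hubs_to_genomes(c("K1", "K2"), ann)
  expect_identical(dim(out$presence), c(3L, 2L))
  expect_identical(unname(out$counts), c(2, 1, 0))
  expect_equal(out$fraction_with_hub, 2 / 3)
  gen <- data.frame(genome_id = c("g1", "g2", "g3"),
                    taxonomy = c("d__B;p__Proteobacteria",
                                 "d__B;p__Proteobacteria",
                                 "d__B;p__Firmicutes"))
  out2 <- map_hubs_to_genomes(c("K1", "K2"), ann, gen)
  bp <- out2$by_phylum
  expect_identical(bp$n[bp$phylum == "Proteobacteria" & bp$has_hub == "TRUE"],
                   2L)
})

test_that("hub_sensitivity_contrast exact closed form", {
  counts <- stats::setNames(c(1, 2, 0, 0), c("g1", "g2", "g3", "g4"))
  tc <- data.frame(taxon_id = c("g1", "g2", "g3", "g4"),
                   spearman_rho = c(0.1, 0.2, -0.8, 0.9))
  res <- hub_sensitivity_contrast(counts, tc)
  expect_identical(c(res$n_with, res$n_without), c(2L, 2L))
  expect_equal(res$statistic, 0)          # hub carriers have the lower |rho|
  expect_equal(res$p, 1 / 3)              # 2 of C(4,2)=6 splits as extreme
  expect_equal(res$median_with, 0.15)
  expect_equal(res$median_without, 0.85)
})
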