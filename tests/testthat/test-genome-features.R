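test_that("redundancy_index closed forms", {
  # 3 distinct KOs with copy counts (2, 1, 1): 3 unique / 4 total = 3/4
  r <- redundancy_index(c("K1", "K2", "K3"), c(2L, 1L, 1L))
  expect_identical(r$n_unique, 3L)
  expect_identical(r$n_total, 4L)
  expect_equal(r$index, 3 / 4)
  expect_equal(redundancy_index(c("K1", "K2"))$index, 1)
  expect_error(redundancy_index(c("K1"), c(1L, 2L)), "align")
})

test_that("genome_profiles aggregates counts and attaches classes", {
  ann <- data.frame(genome_id = c("g1", "g1", "g1", "g2"),
                    ko_id = c("K1", "K1", "K2", "K3"),
                    copy_count = c(1L, 1L, 2L, 1L))
  gen <- data.frame(genome_id = c("g1", "g2", "g3"),
                    est_genome_size_bp = c(3e6, 4e6, 5e6),
                    gc_fraction = c(0.5, 0.6, 0.4),
                    completeness_pct = c(95, 80, 70),
                    taxonomy = "d__Bacteria;p__Proteobacteria")
  cls <- data.frame(taxon_id = c("g1", "g2"),
                    class = c("generalist", "specialist"))
  expect_warning(prof <- genome_profiles(ann, gen, cls), "1 genome")
  expect_identical(nrow(prof), 2L)
  expect_identical(prof$n_unique_ko[prof$genome_id == "g1"], 2L)
  expect_identical(prof$n_total_ko[prof$genome_id == "g1"], 4L)
  expect_equal(prof$redundancy_index[prof$genome_id == "g1"], 0.5)
  expect_identical(prof$class, c("generalist", "specialist"))
  expect_identical(prof$phylum, rep("Proteobacteria", 2))
})

test_that("unique_vs_total_fit slope approximates 1 / (1 + duplication)", {
  # with every KO duplicated at rate d, total = unique * (1 + d) exactly,
  # so the regression slope of unique on total is 1 / (1 + d)
  set.seed(11)
  u <- sample(100:400, 40)
  prof <- data.frame(n_unique_ko = u, n_total_ko = round(u * 1.3),
                     class = "generalist", completeness_pct = 90)
  fit <- unique_vs_total_fit(prof)
  expect_equal(fit$slope, 1 / 1.3, tolerance = 0.01)
  expect_true(fit$r2 > 0.99)
  expect_error(unique_vs_total_fit(prof[1:2, ]), "at least 3")
})

test_that("wilcox enumeration matches closed form and stats::wilcox.test", {
  res <- cryonet:::wilcox_exact_enum(1:3, 4:6)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)   # 2 of the 20 subsets are as extreme
  set.seed(4)
  for (k in 1:5) {
    x <- rnorm(6); y <- rnorm(5, 1)
    mine <- cryonet:::wilcox_exact_enum(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("feature_contrast switches between exact and normal methods", {
  prof <- data.frame(class = rep(c("generalist", "specialist"), each = 4),
                     est_genome_size_bp = c(5, 6, 7, 8, 1, 2, 3, 4) * 1e6)
  fc <- feature_contrast(prof, "est_genome_size_bp")
  expect_identical(fc$method, "exact")
  expect_equal(fc$statistic, 16)          # all 16 pairs favor generalists
  expect_equal(fc$p, 2 / choose(8, 4))
  big <- data.frame(class = rep(c("generalist", "specialist"), each = 15),
                    gc_fraction = c(rnorm(15, 0.6, 0.01),
                                    rnorm(15, 0.4, 0.01)))
  expect_identical(feature_contrast(big, "gc_fraction")$method, "normal")
  expect_error(feature_contrast(prof, "nope"), "unknown feature")
})

test_that("diffslope_test is deterministic, bounded and detects contrasts", {
  set.seed(21)
  x <- runif(30, 0, 10)
  a <- data.frame(x = x, y = 2 * x + rnorm(30, 0, 0.3))
  b <- data.frame(x = x, y = 0.5 * x + rnorm(30, 0, 0.3))
  d1 <- diffslope_test(a, b, 199L, seed = 5L)
  d2 <- diffslope_test(a, b, 199L, seed = 5L)
  expect_identical(d1$p_value, d2$p_value)
  expect_equal(d1$slope_a, 2, tolerance = 0.1)
  expect_equal(d1$slope_b, 0.5, tolerance = 0.1)
  expect_equal(d1$p_value, 1 / 200)       # smallest attainable p
  same <- diffslope_test(a, a, 99L, seed = 1L)
  expect_true(same$p_value > 0.5)
  expect_true(same$p_value >= 1 / 100)
})

test_that("per_phylum_contrast tests only sufficiently filled phyla", {
  prof <- data.frame(
    phylum = c(rep("A", 6), rep("B", 3)),
    class = c(rep(c("generalist", "specialist"), 3),
              "specialist", "specialist", "specialist"),
    redundancy_index = c(0.9, 0.5, 0.95, 0.55, 0.85, 0.6, 0.5, 0.5, 0.5))
  out <- per_phylum_contrast(prof, "redundancy_index")
  expect_identical(out$tested, c(TRUE, FALSE))
  out2 <- per_phylum_contrast(prof, "redundancy_index",
                              exclude_specialist_only = TRUE)
  expect_identical(out2$phylum, "A")
})
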