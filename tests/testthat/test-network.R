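# two clean correlation blocks used across the network tests
make_blocks <- function(n_samples = 40, sizes = c(15, 12), noise = 0.3,
                        seed = 5) {
  set.seed(seed)
  f <- matrix(rnorm(n_samples * length(sizes)), n_samples)
  x <- do.call(rbind, lapply(seq_along(sizes), function(b) {
    t(replicate(sizes[b], f[, b] + rnorm(n_samples, 0, noise)))
  }))
  dimnames(x) <- list(sprintf("K%03d", seq_len(sum(sizes))),
                      sprintf("S%02d", seq_len(n_samples)))
  list(x = x, truth = rep(seq_along(sizes), sizes), factors = f)
}

test_that("prevalence_filter keeps exactly the sufficiently present rows", {
  m <- matrix(c(rep(1, 10),
                c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0),
                c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0)),
              3, 10, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), sprintf("s%02d", 1:10)))
  kept <- suppressMessages(prevalence_filter(abundance_table(m), 0.70))
  expect_identical(rownames(kept), c("a", "b"))   # need >= 7 of 10
  expect_error(suppressMessages(
    prevalence_filter(abundance_table(m * 0 + c(0, 0, 0)), 0.7)),
    "no features survive")
})

test_that("correlation_matrix is symmetric and drops constant rows", {
  bl <- make_blocks()
  r <- correlation_matrix(bl$x)
  expect_identical(r, t(r))
  expect_equal(unname(diag(r)), rep(1, nrow(bl$x)))
  expect_equal(r[1, 2], brute_cor(bl$x[1, ], bl$x[2, ]), tolerance = 1e-12)
  withcst <- rbind(bl$x, cst = rep(2, ncol(bl$x)))
  expect_warning(r2 <- correlation_matrix(withcst), "zero-variance")
  expect_false("cst" %in% rownames(r2))
})

test_that("TOM closed form on a uniform triangle and against brute force", {
  # triangle with all off-diagonal adjacency a: tom_ij = a(a + 1)/(a + 1) = a
  for (a in c(0.2, 0.5, 0.9)) {
    adj <- matrix(a, 3, 3); diag(adj) <- 1
    tom <- topological_overlap(adj)
    expect_equal(tom[1, 2], a, tolerance = 1e-12)
    expect_equal(unname(diag(tom)), rep(1, 3))
  }
  set.seed(8)
  r <- matrix(runif(12 * 12, -1, 1), 12); r <- (r + t(r)) / 2; diag(r) <- 1
  adj <- adjacency_matrix(r, 3)
  expect_equal(topological_overlap(adj), brute_tom(adj), tolerance = 1e-12)
  expect_error(topological_overlap(matrix(c(1, 2, 2, 1), 2)), "\\[0, 1\\]")
})

test_that("pick_soft_threshold honours force and returns a full fit table", {
  bl <- make_blocks()
  r <- correlation_matrix(bl$x)
  pick <- pick_soft_threshold(r, powers = 1:6, force = 7L)
  expect_identical(pick$power, 7L)
  expect_identical(nrow(pick$fit_table), 6L)
  expect_true(all(is.finite(pick$fit_table$mean_k)))
  free <- pick_soft_threshold(r, powers = 1:6, fit_target = -Inf)
  expect_identical(free$power, 1L)   # smallest power reaching the target
})

test_that("module_eigengene matches dense SVD and orients positively", {
  bl <- make_blocks()
  sub <- bl$x[bl$truth == 1, ]
  eg <- module_eigengene(sub)
  xs <- t(scale(t(sub)))
  sv <- svd(xs)
  expect_true(abs(cor(eg$eigengene, sv$v[, 1])) > 0.9999)
  expect_equal(eg$var_explained, sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
  expect_true(cor(eg$eigengene, colMeans(xs)) > 0)   # sign orientation
  expect_equal(stats::sd(eg$eigengene), 1)
  # rank-1 module: variance explained is exactly 1
  rank1 <- rbind(a = 1:10, b = 2 * (1:10) + 3)
  colnames(rank1) <- sprintf("s%02d", 1:10)
  expect_equal(module_eigengene(rank1)$var_explained, 1)
})

test_that("static cut plus kME rescue recovers two clean blocks exactly", {
  bl <- make_blocks()
  r <- correlation_matrix(bl$x)
  tom <- topological_overlap(adjacency_matrix(r, 7))
  det <- detect_modules(tom, min_module_size = 10L)
  # the static cut alone may leave stragglers grey but finds both blocks
  expect_identical(setdiff(sort(unique(det$labels)), "grey"),
                   c("blue", "turquoise"))
  expect_true(adjusted_rand_index(det$labels, bl$truth) > 0.8)
  # every assigned feature sits in the right block
  for (m in c("turquoise", "blue")) {
    expect_identical(length(unique(bl$truth[det$labels == m])), 1L)
  }
  # the kME rescue stage completes the recovery
  me <- cryonet:::eigengene_matrix(bl$x, det$labels)
  out <- reassign_grey(bl$x, det$labels, me, threshold = 0.7)
  expect_equal(adjusted_rand_index(out, bl$truth), 1)
  expect_identical(as.integer(sort(table(out), decreasing = TRUE)),
                   c(15L, 12L))
  expect_identical(names(sort(table(out), decreasing = TRUE)),
                   c("turquoise", "blue"))   # size-ordered palette
})

test_that("detect_modules grey-labels undersized structure", {
  bl <- make_blocks(sizes = c(15, 4))   # second block below min size
  r <- correlation_matrix(bl$x)
  tom <- topological_overlap(adjacency_matrix(r, 7))
  det <- detect_modules(tom, min_module_size = 10L)
  expect_identical(unname(det$labels[bl$truth == 2]), rep("grey", 4))
  expect_true(sum(det$labels[bl$truth == 1] == "turquoise") >= 10)
  expect_identical(setdiff(unique(det$labels), "grey"), "turquoise")
})

test_that("merge_similar_modules merges modules sharing a driver", {
  set.seed(9)
  n <- 40
  f <- rnorm(n)
  g <- rnorm(n)
  x <- rbind(t(replicate(12, f + rnorm(n, 0, 0.2))),
             t(replicate(12, f + rnorm(n, 0, 0.2))),
             t(replicate(12, g + rnorm(n, 0, 0.2))))
  dimnames(x) <- list(sprintf("K%03d", 1:36), sprintf("S%02d", 1:n))
  labels <- stats::setNames(rep(c("blue", "brown", "turquoise"), each = 12),
                            rownames(x))
  merged <- merge_similar_modules(x, labels, similarity_threshold = 0.75)
  expect_identical(length(unique(merged$labels)), 2L)
  expect_identical(unname(merged$labels[1]), unname(merged$labels[13]))
  expect_false(merged$labels[1] == merged$labels[25])
})

test_that("reassign_grey rescues strong members and leaves noise grey", {
  bl <- make_blocks()
  labels <- stats::setNames(
    c("turquoise", "blue")[bl$truth], rownames(bl$x))
  noise <- matrix(rnorm(2 * ncol(bl$x)), 2,
                  dimnames = list(c("N1", "N2"), colnames(bl$x)))
  x <- rbind(bl$x, noise)
  labels <- c(labels, N1 = "grey", N2 = "grey")
  labels[1] <- "grey"                      # a true member mislabeled grey
  me <- cryonet:::eigengene_matrix(x, labels)
  out <- reassign_grey(x, labels, me, threshold = 0.7)
  expect_identical(unname(out["K001"]), "turquoise")
  expect_identical(unname(out[c("N1", "N2")]), c("grey", "grey"))
  expect_identical(out[names(out) != "K001"], labels[names(labels) != "K001"])
})

test_that("module_membership is the plain Pearson kME", {
  bl <- make_blocks()
  labels <- stats::setNames(c("turquoise", "blue")[bl$truth],
                            rownames(bl$x))
  me <- cryonet:::eigengene_matrix(bl$x, labels)
  kme <- module_membership(bl$x, me)
  expect_equal(kme["K001", "turquoise"],
               cor(bl$x["K001", ], me[, "turquoise"]), tolerance = 1e-12)
  own <- kme[cbind(seq_len(nrow(bl$x)),
                   match(labels, colnames(kme)))]
  other <- kme[cbind(seq_len(nrow(bl$x)),
                     3L - match(labels, colnames(kme)))]
  expect_true(all(own > abs(other)))
})

test_that("module_trait_correlation matches cor.test", {
  bl <- make_blocks()
  labels <- stats::setNames(c("turquoise", "blue")[bl$truth],
                            rownames(bl$x))
  me <- cryonet:::eigengene_matrix(bl$x, labels)
  met <- data.frame(sample_id = rownames(me),
                    radiation = bl$factors[, 1] + rnorm(40, 0, 0.1),
                    temperature = rnorm(40))
  mt <- module_trait_correlation(me, met)
  ref <- stats::cor.test(me[, "turquoise"], met$radiation)
  row <- mt[mt$module == "turquoise" & mt$covariate == "radiation", ]
  expect_equal(row$pearson_r, unname(ref$estimate))
  expect_equal(row$p_value, ref$p.value)
  expect_true(abs(row$pearson_r) > 0.9)
})
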