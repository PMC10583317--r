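test_that("vif_filter closed forms on orthogonal and collinear designs", {
  set.seed(23)
  x0 <- scale(matrix(rnorm(30 * 3), 30), scale = FALSE)
  X <- as.data.frame(qr.Q(qr(x0)))       # centered orthonormal columns
  names(X) <- c("a", "b", "c")
  out <- vif_filter(X, threshold = 10)
  expect_identical(out$retained, c("a", "b", "c"))
  expect_true(all(abs(out$vif - 1) < 1e-8))     # orthogonal -> VIF exactly 1
  X$d <- X$a + X$b                               # perfectly collinear
  expect_warning(out2 <- vif_filter(X, threshold = 10), "collinear")
  expect_identical(out2$dropped, "d")            # later-listed goes first
  expect_true(all(out2$vif < 10))
})

test_that("hierarchical partition: 2-covariate closed form and exact sum", {
  set.seed(24)
  n <- 30
  x1 <- rnorm(n); x2 <- 0.6 * x1 + rnorm(n, 0, 0.8)
  Y <- rbind(f1 = 2 * x1 + rnorm(n, 0, 0.5),
             f2 = -x2 + rnorm(n, 0, 0.5))
  colnames(Y) <- sprintf("s%02d", 1:n)
  X <- data.frame(x1 = x1, x2 = x2)
  hp <- hierarchical_partition(Y, X)
  # closed form for p = 2: I_1 = (R2_1 + R2_12 - R2_2) / 2
  r2_1 <- cryonet:::canonical_r2(t(Y), X[, "x1", drop = FALSE])
  r2_2 <- cryonet:::canonical_r2(t(Y), X[, "x2", drop = FALSE])
  r2_12 <- cryonet:::canonical_r2(t(Y), X)
  expect_equal(hp$independent_contribution[1], (r2_1 + r2_12 - r2_2) / 2,
               tolerance = 1e-12)
  expect_equal(hp$independent_contribution[2], (r2_2 + r2_12 - r2_1) / 2,
               tolerance = 1e-12)
  # the partition sums exactly to the full-model R^2
  expect_equal(sum(hp$independent_contribution), attr(hp, "total_r2"),
               tolerance = 1e-12)
  expect_equal(sum(hp$independent_contribution_pct), 100, tolerance = 1e-9)
})

test_that("partition sums exactly for more covariates too", {
  set.seed(25)
  n <- 25
  X <- as.data.frame(matrix(rnorm(n * 4), n))
  names(X) <- letters[1:4]
  Y <- rbind(f1 = X$a - X$c + rnorm(n, 0, 0.3),
             f2 = X$b + rnorm(n, 0, 0.3))
  colnames(Y) <- sprintf("s%02d", 1:n)
  hp <- hierarchical_partition(Y, X)
  expect_equal(sum(hp$independent_contribution), attr(hp, "total_r2"),
               tolerance = 1e-12)
})

test_that("rda_fit explains a planted gradient and is seed-stable", {
  set.seed(26)
  n <- 30
  rad <- sort(runif(n, 10, 30))
  Y <- rbind(t(replicate(8, 0.8 * cryonet:::zscore(rad) + rnorm(n, 0, 0.4))),
             t(replicate(8, rnorm(n))))
  dimnames(Y) <- list(sprintf("K%02d", 1:16), sprintf("s%02d", 1:n))
  X <- data.frame(radiation = rad, temperature = rnorm(n))
  r1 <- rda_fit(Y, X, n_permutations = 199L, seed = 4L)
  r2 <- rda_fit(Y, X, n_permutations = 199L, seed = 4L)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$envfit_table$p, r2$envfit_table$p)
  expect_true(r1$explained_fraction > 0.2)
  expect_equal(r1$p_value, 1 / 200)       # strong signal, smallest p
  expect_true(r1$envfit_table$r2[1] > r1$envfit_table$r2[2])
  # explained fraction equals the canonical R^2 of the same regression
  expect_equal(r1$explained_fraction, cryonet:::canonical_r2(t(Y), X),
               tolerance = 1e-10)
})

test_that("mrm recovers a planted distance relation deterministically", {
  set.seed(27)
  n <- 20
  rad <- runif(n, 0, 10)
  noise <- rnorm(n)
  drad <- stats::dist(rad)
  dnoise <- stats::dist(noise)
  dcom <- drad * 0.9 + stats::dist(rnorm(n, 0, 0.5))
  m1 <- mrm(dcom, list(radiation = drad, noise = dnoise),
            n_permutations = 199L, seed = 2L)
  m2 <- mrm(dcom, list(radiation = drad, noise = dnoise),
            n_permutations = 199L, seed = 2L)
  expect_identical(m1$coefficients$p, m2$coefficients$p)
  cf <- m1$coefficients
  expect_equal(cf$p[cf$covariate == "radiation"], 1 / 200)
  expect_true(cf$p[cf$covariate == "noise"] > 0.05)
  expect_true(cf$beta_std[cf$covariate == "radiation"] > 0.8)
  expect_true(all(m1$coefficients$p >= 1 / 200))
  expect_error(mrm(dcom, list(radiation = drad), n_permutations = 9L),
               "at least 99")
})

test_that("taxon_trait_spearman matches cor.test and flags constants", {
  x <- rbind(t1 = c(1, 2, 3, 4, 5), t2 = c(1, 3, 2, 5, 4),
             t3 = rep(2, 5))
  colnames(x) <- sprintf("s%d", 1:5)
  rad <- c(1, 2, 3, 4, 5)
  out <- taxon_trait_spearman(x, rad)
  expect_equal(out$spearman_rho[1], 1)
  expect_equal(out$spearman_rho[2], 0.8)   # hand-computed rank correlation
  expect_true(is.na(out$spearman_rho[3]))
  ref <- suppressWarnings(stats::cor.test(x[2, ], rad, method = "spearman",
                                          exact = FALSE))
  expect_equal(out$p_value[2], ref$p.value)
})

test_that("haversine closed forms", {
  d0 <- haversine_distance(c(46, 46), c(10, 10))
  expect_equal(as.numeric(d0), 0)
  # antipodal points are half the great circle apart: pi * 6371 km
  da <- haversine_distance(c(0, 0), c(0, 180))
  expect_equal(as.numeric(da), pi * 6371, tolerance = 1e-6)
  # one degree of latitude along a meridian: (pi / 180) * 6371 km
  d1 <- haversine_distance(c(45, 46), c(7, 7))
  expect_equal(as.numeric(d1), pi / 180 * 6371, tolerance = 1e-6)
})

test_that("class_aggregate_fit matches lm on the aggregated response", {
  tab <- fixture_table()
  cls <- data.frame(taxon_id = rownames(tab),
                    class = c("generalist", "specialist", "specialist",
                              "generalist", "specialist", "generalist"))
  rad <- c(1, 2, 3, 4, 5)
  out <- class_aggregate_fit(tab, cls, rad)
  agg <- colSums(unclass(tab)[c(1, 4, 6), ])
  ref <- summary(stats::lm(agg ~ rad))
  row <- out[out$class == "generalist" & out$response == "abundance", ]
  expect_equal(row$slope, unname(coef(stats::lm(agg ~ rad))[2]))
  expect_equal(row$r2, ref$r.squared)
  expect_identical(sort(unique(out$response)), c("abundance", "richness"))
})

test_that("distance_decay ranks the gradient above geography by design", {
  set.seed(28)
  n <- 24
  rad <- runif(n, 5, 25)
  lat <- runif(n, 45, 47); lon <- runif(n, 8, 12)
  dcom <- stats::dist(rad) * 0.8 + stats::dist(rnorm(n, 0, 0.6))
  dd <- distance_decay(dcom, rad, lat, lon)
  expect_identical(dd$predictor,
                   c("radiation_difference", "geographic_distance"))
  expect_true(dd$r2[1] > dd$r2[2])
  expect_true(dd$slope[1] > 0)
  ddj <- distance_decay(dcom, rad, lat, lon, joint_mrm = TRUE,
                        n_permutations = 99L, seed = 1L)
  expect_s3_class(attr(ddj, "mrm")$coefficients, "data.frame")
})
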