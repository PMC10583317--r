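#' Iterative variance-inflation-factor filtering
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing covariate j on the others; the
#' covariate with the largest VIF is dropped repeatedly until all VIFs fall
#' below the threshold (study rule: keep VIF < 10). Perfectly collinear
#' covariates produce infinite VIF; the later-listed one is dropped first.
#'
#' @param covariates data.frame or matrix of numeric covariates (no ids).
#' @param threshold VIF cutoff (default 10).
#' @return list: `retained` (names), `vif` (final per-covariate VIFs),
#'   `dropped` (in drop order).
#' @export
vif_filter <- function(covariates, threshold = 10) {
  X <- as.data.frame(covariates)
  assert_that(ncol(X) >= 2, "need at least 2 covariates")
  assert_that(nrow(X) > ncol(X), "need more samples than covariates")
  vif_of <- function(X) {
    vapply(seq_along(X), function(j) {
      y <- X[[j]]
      fit <- stats::lm(y ~ ., data = X[-j])
      r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  dropped <- character(0)
  while (ncol(X) >= 2) {
    v <- vif_of(X)
    if (all(v < threshold)) break
    worst <- max(which(v == max(v)))   # ties: drop the later-listed
    if (is.infinite(v[worst]))
      warning(sprintf("perfectly collinear covariate dropped: %s",
                      names(X)[worst]))
    dropped <- c(dropped, names(X)[worst])
    X <- X[-worst]
  }
  v <- if (ncol(X) >= 2) vif_of(X) else stats::setNames(1, names(X))
  list(retained = names(X), vif = stats::setNames(v, names(X)),
       dropped = dropped)
}

# canonical R^2: fraction of total variance of Y (samples x features)
# explained by OLS on covariates X (samples x p)
canonical_r2 <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  fitted <- qr.fitted(qrX, Yc)
  sum(fitted^2) / sum(Yc^2)
}

#' Redundancy analysis with permutation tests
#'
#' Constrains the sample x feature CLR community matrix on z-scored
#' covariates via `vegan::rda`. Reports the explained fraction (constrained
#' over total inertia), a global permutation F test, ordination site scores,
#' and per-covariate vector fits from `vegan::envfit` with permutation p.
#'
#' @param clr_community CLR matrix, features x samples.
#' @param covariates data.frame of numeric covariates, rows aligned with
#'   samples (after VIF filtering).
#' @param n_permutations permutations for both tests (study: 999).
#' @param seed RNG seed for the permutations.
#' @return list: explained_fraction, F, p_value, site_scores, envfit_table
#'   (covariate, r2, p), rda (the vegan object).
#' @export
rda_fit <- function(clr_community, covariates, n_permutations = 999L,
                    seed = 1L) {
  Y <- t(as.matrix(clr_community))          # samples x features
  X <- as.data.frame(lapply(as.data.frame(covariates), zscore))
  assert_that(nrow(Y) == nrow(X), "samples of community and covariates differ")
  assert_that(nrow(Y) > ncol(X), "need more samples than covariates")
  ord <- vegan::rda(Y ~ ., data = X)
  explained <- ord$CCA$tot.chi / ord$tot.chi
  set.seed(seed)
  an <- vegan::anova.cca(ord, permutations = n_permutations)
  scores <- vegan::scores(ord, display = "sites",
                          choices = seq_len(min(2, ord$CCA$rank)))
  set.seed(seed)
  ef <- vegan::envfit(scores, X, permutations = n_permutations)
  envfit_table <- data.frame(covariate = names(X),
                             r2 = unname(ef$vectors$r),
                             p = unname(ef$vectors$pvals),
                             stringsAsFactors = FALSE)
  list(explained_fraction = explained,
       F = an$F[1], p_value = an$`Pr(>F)`[1],
       site_scores = scores, envfit_table = envfit_table, rda = ord)
}

#' Hierarchical partitioning of RDA explained variation
#'
#' For each covariate, averages its incremental canonical R^2 over all
#' subsets of the other covariates (equal weight per subset size), so the
#' per-covariate independent contributions sum exactly to the full-model
#' explained variation; contributions are also rescaled to percent of the
#' total explained.
#'
#' @param clr_community CLR matrix, features x samples.
#' @param covariates data.frame of numeric covariates (at most 12).
#' @return data.frame: covariate, independent_contribution (R^2 units),
#'   independent_contribution_pct, plus attribute `total_r2`.
#' @export
hierarchical_partition <- function(clr_community, covariates) {
  X <- as.data.frame(covariates)
  p <- ncol(X)
  assert_that(p >= 1, "need at least one covariate")
  assert_that(p <= 12, "more than 12 covariates: subset enumeration refused")
  Y <- t(as.matrix(clr_community))
  # R^2 for every subset, indexed by bitmask
  r2 <- numeric(2^p)
  for (mask in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    r2[mask + 1] <- canonical_r2(Y, X[, idx, drop = FALSE])
  }
  contrib <- numeric(p)
  for (j in seq_len(p)) {
    bit_j <- 2^(j - 1)
    others <- setdiff(seq_len(p), j)
    total <- 0
    # enumerate subsets S of the others; weight 1/(p * choose(p-1, |S|))
    for (mask in 0:(2^(p - 1) - 1)) {
      s_bits <- which(bitwAnd(mask, 2^(seq_len(p - 1) - 1)) > 0)
      S <- others[s_bits]
      m_S <- sum(2^(S - 1))
      inc <- r2[m_S + bit_j + 1] - r2[m_S + 1]
      w <- 1 / (p * choose(p - 1, length(S)))
      total <- total + w * inc
    }
    contrib[j] <- total
  }
  total_r2 <- r2[2^p]
  out <- data.frame(covariate = names(X),
                    independent_contribution = contrib,
                    independent_contribution_pct = 100 * contrib / total_r2,
                    stringsAsFactors = FALSE)
  attr(out, "total_r2") <- total_r2
  out
}

# condensed (lower-triangle) vector from a dist or matrix
as_dist_vec <- function(d) {
  if (inherits(d, "dist")) return(list(vec = as.numeric(d), n = attr(d, "Size")))
  m <- as.matrix(d)
  list(vec = m[lower.tri(m)], n = nrow(m))
}

#' Multiple regression on distance matrices
#'
#' OLS of the standardized community-distance vector on standardized
#' covariate-distance vectors; per-coefficient permutation p-values come
#' from Mantel-style simultaneous row/column permutations of the response
#' distance matrix: `p = (1 + #{|null t| >= |obs t|}) / (n_perm + 1)`.
#'
#' @param community_distance `dist` or square matrix over samples.
#' @param covariate_distances named list of `dist`/matrices over the same
#'   samples.
#' @param n_permutations Mantel permutations (>= 99).
#' @param seed RNG seed.
#' @return list: `coefficients` (data.frame: covariate, beta_std, t, p),
#'   `r2`, `n_permutations`.
#' @export
mrm <- function(community_distance, covariate_distances,
                n_permutations = 999L, seed = 1L) {
  assert_that(n_permutations >= 99, "need at least 99 permutations")
  resp <- as_dist_vec(community_distance)
  n <- resp$n
  preds <- lapply(covariate_distances, function(d) {
    dv <- as_dist_vec(d)
    assert_that(dv$n == n, "distance matrices cover different sample sets")
    dv$vec
  })
  assert_that(stats::sd(resp$vec) > 0, "constant response distance vector")
  X <- do.call(cbind, lapply(preds, zscore))
  colnames(X) <- names(covariate_distances) %||%
    paste0("d", seq_along(covariate_distances))
  yz <- zscore(resp$vec)
  fit <- stats::lm(yz ~ X)
  sm <- summary(fit)
  obs_t <- sm$coefficients[-1, 3]
  beta <- stats::coef(fit)[-1]
  Dm <- as.matrix(community_distance)
  set.seed(seed)
  exceed <- rep(0L, length(obs_t))
  for (k in seq_len(n_permutations)) {
    perm <- sample.int(n)
    Dp <- Dm[perm, perm]
    yp <- zscore(Dp[lower.tri(Dp)])
    smp <- summary(stats::lm(yp ~ X))
    exceed <- exceed + (abs(smp$coefficients[-1, 3]) >= abs(obs_t))
  }
  p <- (1 + exceed) / (n_permutations + 1)
  list(coefficients = data.frame(covariate = colnames(X),
                                 beta_std = unname(beta),
                                 t = unname(obs_t), p = unname(p),
                                 stringsAsFactors = FALSE),
       r2 = sm$r.squared, n_permutations = n_permutations)
}

#' Per-taxon Spearman correlation with radiation
#'
#' Spearman rho with tie-corrected p for every taxon's CLR profile against
#' radiation; constant taxa yield NA.
#'
#' @param clr_community CLR matrix, features x samples.
#' @param radiation vector aligned with the samples.
#' @param classes optional [classify_niche()] output to attach class labels.
#' @return data.frame: taxon_id, spearman_rho, p_value, class, significant.
#' @export
taxon_trait_spearman <- function(clr_community, radiation, classes = NULL) {
  x <- as.matrix(clr_community)
  assert_that(ncol(x) >= 5, "need at least 5 samples")
  assert_that(ncol(x) == length(radiation), "samples and radiation must align")
  rho <- rep(NA_real_, nrow(x)); pv <- rep(NA_real_, nrow(x))
  for (i in seq_len(nrow(x))) {
    if (stats::sd(x[i, ]) == 0) next
    ct <- suppressWarnings(stats::cor.test(x[i, ], radiation,
                                           method = "spearman",
                                           exact = FALSE))
    rho[i] <- unname(ct$estimate); pv[i] <- ct$p.value
  }
  out <- data.frame(taxon_id = rownames(x), spearman_rho = rho, p_value = pv,
                    stringsAsFactors = FALSE)
  if (!is.null(classes))
    out$class <- classes$class[match(out$taxon_id, classes$taxon_id)]
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  out
}

#' Per-class linear fits of cumulative abundance and richness vs radiation
#'
#' Per sample, sums TPM abundance and counts detected taxa within each niche
#' class, then regresses both on radiation.
#'
#' @param table SGB [abundance_table()] (TPM).
#' @param classes [classify_niche()] output (or a truth table with taxon_id,
#'   class).
#' @param radiation vector aligned with the table's samples.
#' @return data.frame: class, response (abundance/richness), slope, r2, p, n.
#' @export
class_aggregate_fit <- function(table, classes, radiation) {
  x <- unclass(as.matrix(table))
  assert_that(ncol(x) == length(radiation), "samples and radiation must align")
  cls <- classes$class[match(rownames(x), classes$taxon_id)]
  out <- list()
  for (cl in unique(stats::na.omit(cls))) {
    rows <- which(cls == cl)
    if (length(rows) == 0) { warning(sprintf("class %s absent", cl)); next }
    agg <- colSums(x[rows, , drop = FALSE])
    rich <- colSums(x[rows, , drop = FALSE] > 0)
    for (resp in c("abundance", "richness")) {
      y <- if (resp == "abundance") agg else rich
      if (stats::var(y) == 0) {
        out[[paste(cl, resp)]] <- data.frame(class = cl, response = resp,
                                             slope = 0, r2 = 0, p = NA_real_,
                                             n = ncol(x))
        next
      }
      fit <- stats::lm(y ~ radiation)
      sm <- summary(fit)
      out[[paste(cl, resp)]] <- data.frame(
        class = cl, response = resp,
        slope = unname(stats::coef(fit)[2]), r2 = sm$r.squared,
        p = sm$coefficients[2, 4], n = ncol(x), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Great-circle distance matrix (haversine, km)
#'
#' @param latitude,longitude degree vectors over samples.
#' @return `dist` object in kilometers (Earth radius 6371 km).
#' @export
haversine_distance <- function(latitude, longitude) {
  pts <- cbind(longitude, latitude)
  m <- geosphere::distm(pts, fun = geosphere::distHaversine) / 1000 *
    (6371 / 6378.137)   # geosphere uses radius 6378137 m; rescale to 6371 km
  stats::as.dist(m)
}

#' Distance decay of community dissimilarity
#'
#' OLS of the community distance on (a) pairwise absolute radiation
#' difference and (b) haversine geographic distance; optionally a joint MRM
#' with both predictors.
#'
#' @param community_distance `dist` over samples.
#' @param radiation vector over samples.
#' @param latitude,longitude optional coordinates; geographic variant is
#'   skipped when missing.
#' @param joint_mrm also run [mrm()] with both predictors (default FALSE).
#' @param ... passed to [mrm()].
#' @return data.frame: predictor, slope, r2, p; attribute `mrm` when
#'   requested.
#' @export
distance_decay <- function(community_distance, radiation, latitude = NULL,
                           longitude = NULL, joint_mrm = FALSE, ...) {
  y <- as_dist_vec(community_distance)$vec
  drad <- as_dist_vec(stats::dist(radiation))$vec
  fit_one <- function(xv, label) {
    fit <- stats::lm(y ~ xv)
    sm <- summary(fit)
    data.frame(predictor = label, slope = unname(stats::coef(fit)[2]),
               r2 = sm$r.squared, p = sm$coefficients[2, 4],
               stringsAsFactors = FALSE)
  }
  out <- fit_one(drad, "radiation_difference")
  dists <- list(radiation_difference = stats::dist(radiation))
  if (!is.null(latitude) && !is.null(longitude)) {
    dgeo <- haversine_distance(latitude, longitude)
    out <- rbind(out, fit_one(as_dist_vec(dgeo)$vec, "geographic_distance"))
    dists$geographic_distance <- dgeo
  }
  if (joint_mrm)
    attr(out, "mrm") <- mrm(community_distance, dists, ...)
  out
}
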