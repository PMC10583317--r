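#' Prevalence filter for abundance tables
#'
#' Keeps features with positive abundance in at least
#' `ceiling(threshold * n_samples)` samples (the study retains KOs present
#' in at least 70% of samples).
#'
#' @param table an [abundance_table()].
#' @param threshold prevalence fraction in (0, 1].
#' @return Filtered [abundance_table()]; kept/dropped counts are messaged.
#' @export
prevalence_filter <- function(table, threshold = 0.70) {
  assert_that(threshold > 0 && threshold <= 1,
              "threshold must lie in (0, 1]")
  x <- unclass(as.matrix(table))
  need <- ceiling(threshold * ncol(x))
  keep <- rowSums(x > 0) >= need
  assert_that(any(keep), "no features survive the prevalence filter")
  message(sprintf("prevalence filter: kept %d of %d features (>= %d samples)",
                  sum(keep), nrow(x), need))
  abundance_table(x[keep, , drop = FALSE])
}

#' Pearson correlation matrix across samples
#'
#' Feature-by-feature Pearson correlation of CLR profiles over samples.
#' Zero-variance features are excluded with a warning.
#'
#' @param clr matrix, features x samples (CLR scale).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(clr) {
  x <- as.matrix(clr)
  assert_that(ncol(x) >= 3, "need at least 3 samples")
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warning(sprintf("excluding %d zero-variance feature(s)", sum(v == 0)))
    x <- x[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(x))
  (r + t(r)) / 2
}

# scale-free topology fit: R^2 of log10 p(k) on log10 k over equal-count
# connectivity bins, signed negative when the slope is positive
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  n_bins <- min(n_bins, length(unique(k)))
  breaks <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(k, breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(NA_real_)
  lx <- log10(dk[ok]); ly <- log10(pk[ok])
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0) return(NA_real_)
  r <- stats::cor(lx, ly)
  if (r > 0) -r^2 else r^2
}

#' Choose the soft-thresholding power
#'
#' For each candidate power, the adjacency is `|r|^beta`, connectivity
#' `k_i = sum_{j != i} a_ij`, and the scale-free fit index is the signed R^2
#' of the log-log regression of the connectivity distribution over
#' equal-count bins. The chosen power is the smallest whose signed R^2
#' reaches `fit_target` (else the argmax). A forced power short-circuits
#' the choice but the fit table is still returned.
#'
#' @param correlation symmetric correlation matrix.
#' @param powers integer grid of candidate powers.
#' @param fit_target signed R^2 target (default 0.80).
#' @param force optional integer power to use regardless of fit (the study
#'   runs at 7).
#' @return list with `power` and `fit_table` (power, r2, mean_k, median_k).
#' @export
pick_soft_threshold <- function(correlation, powers = 1:20,
                                fit_target = 0.80, force = NULL) {
  assert_that(length(powers) > 0, "empty power grid")
  absr <- abs(correlation)
  assert_that(stats::sd(absr[upper.tri(absr)]) > 0,
              "degenerate (constant) correlation matrix")
  fit_table <- data.frame(power = powers, r2 = NA_real_,
                          mean_k = NA_real_, median_k = NA_real_)
  for (i in seq_along(powers)) {
    a <- absr^powers[i]
    diag(a) <- 0
    k <- rowSums(a)
    fit_table$r2[i] <- scale_free_fit(k)
    fit_table$mean_k[i] <- mean(k)
    fit_table$median_k[i] <- stats::median(k)
  }
  if (!is.null(force)) return(list(power = as.integer(force),
                                   fit_table = fit_table))
  ok <- which(!is.na(fit_table$r2) & fit_table$r2 >= fit_target)
  power <- if (length(ok) > 0) powers[min(ok)] else
    powers[which.max(fit_table$r2)]
  list(power = as.integer(power), fit_table = fit_table)
}

#' Soft-thresholded adjacency
#'
#' Unsigned network: `a_ij = |r_ij|^beta`, unit diagonal.
#'
#' @param correlation symmetric correlation matrix.
#' @param beta soft power.
#' @return Adjacency matrix in [0, 1].
#' @export
adjacency_matrix <- function(correlation, beta) {
  a <- abs(correlation)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `tom_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' the diagonal is 1. The clustering dissimilarity is `1 - tom`.
#'
#' @param adjacency symmetric matrix with entries in [0, 1].
#' @return TOM matrix of the same shape.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  assert_that(all(a >= 0 & a <= 1), "adjacency entries must lie in [0, 1]")
  diag(a) <- 0
  l <- a %*% a                       # l_ij = sum_u a_iu a_uj (u != i,j since diag 0)
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect modules by tree cut on TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - tom`, then a top-down
#' adaptive cut: candidate static cut heights are the midpoints between
#' consecutive merge heights of the dendrogram; at each height, subtrees
#' with at least `min_module_size` members become candidate modules. The
#' chosen cut maximizes the number of such modules; ties are broken by the
#' mean silhouette width of the assigned features on the dissimilarity,
#' then by the lower height, so the cut is deterministic. Features in
#' undersized branches are labeled `"grey"`; module labels are color-style
#' names ordered by size.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param min_module_size minimum features per module (study default 50).
#' @param height_grid optional quantile probabilities restricting the
#'   scanned heights (default NULL = all merge-height midpoints).
#' @return list: `labels` (named character vector, `"grey"` = unassigned),
#'   `dendrogram` (hclust), `cut_height`.
#' @export
detect_modules <- function(tom, min_module_size = 50L, height_grid = NULL) {
  assert_that(min_module_size >= 2, "min_module_size must be >= 2")
  d <- 1 - tom
  ids <- rownames(tom) %||% as.character(seq_len(nrow(tom)))
  if (nrow(tom) < min_module_size) {
    warning("fewer features than min_module_size; all features grey")
    labels <- stats::setNames(rep("grey", nrow(tom)), ids)
    return(list(labels = labels, dendrogram = NULL, cut_height = NA_real_))
  }
  dd <- stats::as.dist(d)
  tree <- stats::hclust(dd, method = "average")
  hs <- sort(unique(tree$height))
  heights <- if (length(hs) > 1) (hs[-1] + hs[-length(hs)]) / 2 else hs
  if (!is.null(height_grid)) {
    heights <- unique(stats::quantile(tree$height, probs = height_grid,
                                      type = 7))
  }
  # pass 1: number of big clusters per height
  n_big <- vapply(heights, function(h) {
    sizes <- table(stats::cutree(tree, h = h))
    sum(sizes >= min_module_size)
  }, numeric(1))
  if (max(n_big) == 0) {
    warning("no branch reaches min_module_size; all features grey")
    labels <- stats::setNames(rep("grey", nrow(tom)), ids)
    return(list(labels = labels, dendrogram = tree, cut_height = NA_real_))
  }
  # pass 2: silhouette tie-break among the best heights
  cand <- heights[n_big == max(n_big)]
  dmat_full <- as.matrix(dd)
  best <- NULL
  for (h in cand) {
    cl <- stats::cutree(tree, h = h)
    sizes <- table(cl)
    big <- as.integer(names(sizes)[sizes >= min_module_size])
    assigned <- cl %in% big
    sil <- 0
    if (length(big) >= 2) {
      sw <- cluster::silhouette(cl[assigned],
                                dmatrix = dmat_full[assigned, assigned,
                                                    drop = FALSE])
      sil <- mean(sw[, "sil_width"])
    }
    if (is.null(best) || sil > best$sil + 1e-12) {
      best <- list(sil = sil, h = h, cl = cl, big = big)
    }
  }
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
               "lightgreen", "lightyellow", "royalblue")
  sizes <- sort(table(best$cl[best$cl %in% best$big]), decreasing = TRUE)
  name_of <- stats::setNames(
    c(palette, paste0("module", seq_len(max(0, length(sizes) - length(palette)))))[
      seq_along(sizes)],
    names(sizes))
  labels <- rep("grey", length(best$cl))
  hit <- as.character(best$cl) %in% names(name_of)
  labels[hit] <- name_of[as.character(best$cl)[hit]]
  names(labels) <- ids
  list(labels = labels, dendrogram = tree, cut_height = best$h)
}

#' Module eigengene
#'
#' Rows (features) are standardized; the eigengene is the first right
#' singular vector over samples, scaled to unit variance and sign-oriented
#' so that it correlates nonnegatively with the module's mean standardized
#' profile. The proportion of variance explained by the first component is
#' reported.
#'
#' @param clr_submatrix CLR matrix restricted to one module's features.
#' @return list: `eigengene` (named vector over samples), `var_explained`.
#' @export
module_eigengene <- function(clr_submatrix) {
  x <- as.matrix(clr_submatrix)
  assert_that(nrow(x) >= 1, "module must contain at least one feature")
  xs <- t(scale(t(x)))
  assert_that(!anyNA(xs), "constant feature profile in module")
  if (nrow(xs) == 1) {
    e <- as.numeric(xs)
    return(list(eigengene = stats::setNames(e / stats::sd(e), colnames(x)),
                var_explained = 1))
  }
  sv <- svd(xs, nu = 0, nv = 1)
  e <- sv$v[, 1]
  mean_profile <- colMeans(xs)
  if (stats::cor(e, mean_profile) < 0) e <- -e
  e <- e / stats::sd(e)
  list(eigengene = stats::setNames(e, colnames(x)),
       var_explained = sv$d[1]^2 / sum(sv$d^2))
}

# eigengene matrix (samples x modules) for all non-grey modules
eigengene_matrix <- function(clr, labels) {
  mods <- setdiff(unique(labels), "grey")
  assert_that(length(mods) > 0, "no modules to summarize")
  me <- sapply(mods, function(m) {
    module_eigengene(clr[names(labels)[labels == m], , drop = FALSE])$eigengene
  })
  rownames(me) <- colnames(clr)
  me
}

#' Merge modules with highly similar eigengenes
#'
#' Modules whose eigengene correlation exceeds `similarity_threshold`
#' (dissimilarity `1 - cor` below `1 - threshold`) are merged by
#' average-linkage clustering of eigengenes; eigengenes are recomputed after
#' each merge round until stable. Grey is never merged.
#'
#' @param clr CLR matrix (features x samples).
#' @param labels module labels from [detect_modules()].
#' @param similarity_threshold eigengene correlation above which modules
#'   merge (study default 0.75).
#' @return list: `labels` (merged), `eigengenes` (samples x modules matrix),
#'   `var_explained` per module.
#' @export
merge_similar_modules <- function(clr, labels, similarity_threshold = 0.75) {
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    me <- eigengene_matrix(clr, labels)
    cc <- stats::cor(me)
    dd <- stats::as.dist(1 - cc)
    tree <- stats::hclust(dd, method = "average")
    grp <- stats::cutree(tree, h = 1 - similarity_threshold)
    if (max(grp) == length(mods)) break   # nothing to merge
    sizes <- table(labels)[names(grp)]
    for (g in unique(grp)) {
      members <- names(grp)[grp == g]
      if (length(members) < 2) next
      keep <- members[which.max(sizes[members])]
      labels[labels %in% members] <- keep
    }
  }
  mods <- setdiff(unique(labels), "grey")
  me <- eigengene_matrix(clr, labels)
  ve <- vapply(mods, function(m) {
    module_eigengene(clr[names(labels)[labels == m], , drop = FALSE])$var_explained
  }, numeric(1))
  list(labels = labels, eigengenes = me[, mods, drop = FALSE],
       var_explained = ve)
}

#' Reassign unassigned features by module membership
#'
#' After the static cut, features left `"grey"` whose kME with some module
#' eigengene exceeds `threshold` are moved into the module of their highest
#' kME (the membership-based rescue stage of adaptive tree cutting).
#' Assigned features are never moved.
#'
#' @param clr CLR matrix (features x samples).
#' @param labels module labels (with `"grey"` for unassigned).
#' @param eigengenes samples x modules eigengene matrix.
#' @param threshold minimum kME for rescue (study default 0.7).
#' @return Updated label vector.
#' @export
reassign_grey <- function(clr, labels, eigengenes, threshold = 0.7) {
  grey_ids <- names(labels)[labels == "grey"]
  if (length(grey_ids) == 0 || ncol(eigengenes) == 0) return(labels)
  kme <- module_membership(clr[grey_ids, , drop = FALSE], eigengenes)
  kme[is.na(kme)] <- -Inf
  best <- max.col(kme, ties.method = "first")
  best_val <- kme[cbind(seq_along(grey_ids), best)]
  move <- best_val > threshold
  labels[grey_ids[move]] <- colnames(kme)[best[move]]
  labels
}

#' Module membership (kME)
#'
#' Pearson correlation of every feature's CLR profile with every module
#' eigengene. Zero-variance profiles yield NA with a warning.
#'
#' @param clr CLR matrix (features x samples).
#' @param eigengenes samples x modules eigengene matrix.
#' @return features x modules kME matrix.
#' @export
module_membership <- function(clr, eigengenes) {
  x <- as.matrix(clr)
  me <- as.matrix(eigengenes)
  assert_that(ncol(x) == nrow(me), "samples of clr and eigengenes must align")
  v <- apply(x, 1, stats::var)
  kme <- matrix(NA_real_, nrow(x), ncol(me),
                dimnames = list(rownames(x), colnames(me)))
  if (any(v == 0)) warning("zero-variance profiles: kME emitted as NA")
  ok <- v > 0
  kme[ok, ] <- stats::cor(t(x[ok, , drop = FALSE]), me)
  kme
}

#' Module eigengene vs covariate correlations
#'
#' Pearson r and two-sided t-test p for every module x covariate pair.
#'
#' @param eigengenes samples x modules matrix (rownames = sample ids).
#' @param meteo meteorological data.frame with `sample_id` plus covariates.
#' @return data.frame: module, covariate, pearson_r, p_value.
#' @export
module_trait_correlation <- function(eigengenes, meteo) {
  me <- as.matrix(eigengenes)
  idx <- match(rownames(me), meteo$sample_id)
  assert_that(!anyNA(idx), "sample ids of eigengenes and meteo do not align")
  covs <- setdiff(names(meteo), "sample_id")
  out <- expand.grid(module = colnames(me), covariate = covs,
                     stringsAsFactors = FALSE)
  out$pearson_r <- NA_real_; out$p_value <- NA_real_
  for (i in seq_len(nrow(out))) {
    ct <- stats::cor.test(me[, out$module[i]],
                          meteo[[out$covariate[i]]][idx])
    out$pearson_r[i] <- unname(ct$estimate)
    out$p_value[i] <- ct$p.value
  }
  out
}

#' Build the full KO co-occurrence network
#'
#' Convenience wrapper running prevalence filtering, zero replacement, CLR,
#' correlation, soft-threshold choice, TOM, module detection, merging,
#' eigengenes and kME with the study defaults.
#'
#' @param ko_table KO [abundance_table()] (TPM).
#' @param config a [run_config()].
#' @return list with clr, correlation, power, fit_table, tom, modules
#'   (labels), eigengenes, var_explained, kme, dendrogram.
#' @export
build_network <- function(ko_table, config = run_config()) {
  filtered <- prevalence_filter(ko_table, config$prevalence_threshold)
  clr <- clr_transform(czm_replace(filtered))
  r <- correlation_matrix(clr)
  clr <- clr[rownames(r), , drop = FALSE]
  pick <- pick_soft_threshold(r, config$soft_power_grid,
                              config$scale_free_target,
                              force = config$soft_power)
  a <- adjacency_matrix(r, pick$power)
  tom <- topological_overlap(a)
  det <- detect_modules(tom, config$min_module_size, config$cut_height_grid)
  merged <- merge_similar_modules(clr, det$labels, config$merge_similarity)
  labels <- reassign_grey(clr, merged$labels, merged$eigengenes,
                          config$kme_reassign_threshold)
  mods <- setdiff(unique(labels), "grey")
  me <- eigengene_matrix(clr, labels)[, mods, drop = FALSE]
  ve <- vapply(mods, function(m) {
    module_eigengene(clr[names(labels)[labels == m], , drop = FALSE])$var_explained
  }, numeric(1))
  kme <- module_membership(clr, me)
  list(clr = clr, correlation = r, power = pick$power,
       fit_table = pick$fit_table, tom = tom, modules = labels,
       eigengenes = me, var_explained = ve,
       kme = kme, dendrogram = det$dendrogram, cut_height = det$cut_height)
}
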