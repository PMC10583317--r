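#' Gene redundancy index of one genome
#'
#' The ratio of distinct KO identifiers to the total number of KO-annotated
#' genes (sum of copy counts). 1 means no duplicated function; lower values
#' mean more within-genome gene duplication.
#'
#' @param ko_ids character vector of KO identifiers.
#' @param copy_counts integer copy count per KO (default all 1).
#' @return list with n_unique, n_total, index.
#' @export
redundancy_index <- function(ko_ids, copy_counts = rep(1L, length(ko_ids))) {
  assert_that(length(ko_ids) == length(copy_counts),
              "ko_ids and copy_counts must align")
  assert_that(length(ko_ids) >= 1 && sum(copy_counts) >= 1,
              "genome has no KO annotations")
  n_unique <- length(unique(ko_ids))
  n_total <- sum(copy_counts)
  list(n_unique = n_unique, n_total = n_total, index = n_unique / n_total)
}

#' Build genome profiles from annotations and metadata
#'
#' Joins genome metadata with per-genome unique/total KO counts and the gene
#' redundancy index; genomes without any KO annotation are dropped with a
#' warning. `duplication_index = 1 - redundancy_index` is also emitted so
#' both readings of the ratio are inspectable.
#'
#' @param annotations data.frame (genome_id, ko_id, copy_count).
#' @param genomes genome metadata data.frame.
#' @param classes optional [classify_niche()] output to attach class labels.
#' @return data.frame of genome profiles.
#' @export
genome_profiles <- function(annotations, genomes, classes = NULL) {
  agg_u <- stats::aggregate(ko_id ~ genome_id, annotations,
                            function(k) length(unique(k)))
  agg_t <- stats::aggregate(copy_count ~ genome_id, annotations, sum)
  prof <- merge(genomes, merge(agg_u, agg_t, by = "genome_id"),
                by = "genome_id", all.x = TRUE)
  missing <- is.na(prof$ko_id)
  if (any(missing)) {
    warning(sprintf("%d genome(s) without KO annotations excluded",
                    sum(missing)))
    prof <- prof[!missing, , drop = FALSE]
  }
  names(prof)[names(prof) == "ko_id"] <- "n_unique_ko"
  names(prof)[names(prof) == "copy_count"] <- "n_total_ko"
  prof$redundancy_index <- prof$n_unique_ko / prof$n_total_ko
  prof$duplication_index <- 1 - prof$redundancy_index
  if (!is.null(classes)) {
    prof$class <- classes$class[match(prof$genome_id, classes$taxon_id)]
  }
  prof$phylum <- parse_rank(prof$taxonomy, "p")
  rownames(prof) <- NULL
  prof
}

#' OLS fit of unique KO count on total KO count
#'
#' @param profiles output of [genome_profiles()].
#' @param group optional niche class to subset to.
#' @param completeness_bins optional numeric breaks to stratify fits by
#'   genome completeness (e.g. `c(50, 70, 90, 100)`).
#' @return data.frame with group, n, slope, intercept, r2, p (slope t-test);
#'   one row per completeness stratum when bins are given.
#' @export
unique_vs_total_fit <- function(profiles, group = NULL,
                                completeness_bins = NULL) {
  df <- profiles
  if (!is.null(group)) df <- df[df$class == group, , drop = FALSE]
  fit_one <- function(d, label) {
    assert_that(nrow(d) >= 3, "need at least 3 genomes for a fit")
    assert_that(stats::var(d$n_total_ko) > 0,
                "zero variance in total KO count; singular fit")
    fit <- stats::lm(n_unique_ko ~ n_total_ko, data = d)
    sm <- summary(fit)
    data.frame(group = label, n = nrow(d),
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r2 = sm$r.squared,
               p = sm$coefficients[2, 4], stringsAsFactors = FALSE)
  }
  label <- group %||% "all"
  if (is.null(completeness_bins)) return(fit_one(df, label))
  bin <- cut(df$completeness_pct, completeness_bins, include.lowest = TRUE,
             right = FALSE)
  out <- lapply(levels(bin), function(b) {
    d <- df[!is.na(bin) & bin == b, , drop = FALSE]
    if (nrow(d) < 3) return(NULL)
    cbind(fit_one(d, label), completeness_bin = b)
  })
  do.call(rbind, out)
}

#' Permutation test for a difference in regression slopes
#'
#' Fits OLS slopes to two point sets, then builds a null for the slope
#' difference by randomly reassigning points between the groups (sizes
#' preserved) and refitting. Two-sided p = (1 + #{|null| >= |observed|}) /
#' (n_permutations + 1).
#'
#' @param points_a,points_b data.frames (or 2-col matrices) with x then y.
#' @param n_permutations permutation count (default 999).
#' @param seed RNG seed.
#' @return list: slope_a, slope_b, observed_diff, n_permutations, p_value.
#' @export
diffslope_test <- function(points_a, points_b, n_permutations = 999L,
                           seed = 1L) {
  a <- as.data.frame(points_a); b <- as.data.frame(points_b)
  names(a)[1:2] <- names(b)[1:2] <- c("x", "y")
  assert_that(nrow(a) >= 3 && nrow(b) >= 3,
              "each group needs at least 3 points")
  slope <- function(d) {
    sx <- stats::var(d$x)
    if (sx == 0) return(NA_real_)
    stats::cov(d$x, d$y) / sx
  }
  obs <- slope(a) - slope(b)
  assert_that(is.finite(obs), "singular fit in observed groups")
  pooled <- rbind(a, b)
  na <- nrow(a); ntot <- nrow(pooled)
  set.seed(seed)
  null <- numeric(n_permutations)
  redraws <- 0L
  for (k in seq_len(n_permutations)) {
    repeat {
      idx <- sample.int(ntot, na)
      d <- slope(pooled[idx, ]) - slope(pooled[-idx, ])
      if (is.finite(d)) break
      redraws <- redraws + 1L
    }
    null[k] <- d
  }
  if (redraws > 0.01 * n_permutations)
    warning(sprintf("%d singular permutations redrawn", redraws))
  p <- (1 + sum(abs(null) >= abs(obs))) / (n_permutations + 1)
  list(slope_a = slope(a), slope_b = slope(b), observed_diff = obs,
       n_permutations = n_permutations, p_value = p)
}

# exact two-sided Mann-Whitney by complete enumeration (handles ties)
wilcox_exact_enum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2   # U statistic for x
  mu <- nx * (n - nx) / 2
  combos <- utils::combn(n, nx)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  tol <- 1e-9
  p <- mean(abs(u_all - mu) >= abs(obs - mu) - tol)
  list(statistic = obs, p_value = p)
}

#' Wilcoxon rank-sum contrast of a genome feature between two classes
#'
#' Exact p by complete enumeration when both groups have at most 10 genomes
#' (ties handled); otherwise the tie-corrected normal approximation with
#' continuity correction. Group means and SDs are reported alongside.
#'
#' @param profiles output of [genome_profiles()] with a `class` column.
#' @param feature column name, e.g. `"est_genome_size_bp"`, `"gc_fraction"`,
#'   `"redundancy_index"`.
#' @param groups length-2 character vector of classes to contrast.
#' @return data.frame with statistic (U for the first group), p, group
#'   means/sds/sizes.
#' @export
feature_contrast <- function(profiles, feature,
                             groups = c("generalist", "specialist")) {
  assert_that(feature %in% names(profiles),
              sprintf("unknown feature '%s'", feature))
  x <- profiles[[feature]][profiles$class == groups[1]]
  y <- profiles[[feature]][profiles$class == groups[2]]
  assert_that(length(x) >= 2 && length(y) >= 2,
              "each group needs at least 2 genomes")
  if (length(x) <= 10 && length(y) <= 10) {
    res <- wilcox_exact_enum(x, y)
    u <- res$statistic; p <- res$p_value; method <- "exact"
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    u <- unname(wt$statistic); p <- wt$p.value; method <- "normal"
  }
  data.frame(feature = feature, group_a = groups[1], group_b = groups[2],
             n_a = length(x), n_b = length(y), statistic = u, p = p,
             mean_a = mean(x), sd_a = stats::sd(x),
             mean_b = mean(y), sd_b = stats::sd(y),
             method = method, stringsAsFactors = FALSE)
}

#' Per-phylum feature contrasts between niche classes
#'
#' Applies [feature_contrast()] within each phylum holding at least 2
#' genomes of each class; other phyla are reported as untested. With
#' `exclude_specialist_only = TRUE`, phyla absent from the first group are
#' dropped entirely.
#'
#' @inheritParams feature_contrast
#' @param exclude_specialist_only drop phyla with no genomes in `groups[1]`.
#' @return data.frame, one row per phylum, with `tested` flag.
#' @export
per_phylum_contrast <- function(profiles, feature,
                                groups = c("generalist", "specialist"),
                                exclude_specialist_only = FALSE) {
  assert_that("phylum" %in% names(profiles), "phylum labels required")
  phyla <- sort(unique(profiles$phylum))
  if (exclude_specialist_only) {
    present <- unique(profiles$phylum[profiles$class == groups[1]])
    phyla <- intersect(phyla, present)
  }
  out <- lapply(phyla, function(ph) {
    d <- profiles[profiles$phylum == ph, , drop = FALSE]
    na <- sum(d$class == groups[1]); nb <- sum(d$class == groups[2])
    if (na < 2 || nb < 2) {
      return(data.frame(phylum = ph, tested = FALSE, n_a = na, n_b = nb,
                        statistic = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    fc <- feature_contrast(d, feature, groups)
    data.frame(phylum = ph, tested = TRUE, n_a = na, n_b = nb,
               statistic = fc$statistic, p = fc$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
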