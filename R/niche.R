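#' Levins' niche breadth index
#'
#' `B = 1 / sum(p_i^2)` where `p_i` is the taxon's proportional abundance in
#' sample `i`. Ranges from 1 (all abundance in one sample) to the number of
#' samples (perfectly even), and is invariant to rescaling the row.
#'
#' @param abundance_row nonnegative vector of a taxon's abundance over samples.
#' @return Levins' B, a number in `[1, length(abundance_row)]`.
#' @export
levins_index <- function(abundance_row) {
  x <- as.numeric(abundance_row)
  assert_that(all(x >= 0), "abundances must be nonnegative")
  total <- sum(x)
  assert_that(total > 0, "Levins' B is undefined for an all-zero row")
  p <- x / total
  1 / sum(p^2)
}

# discretize a TPM table to integer counts at a fixed per-sample depth;
# nonzero cells are kept nonzero (floor at 1) so the fill is preserved
discretize_counts <- function(table, depth = 10000L) {
  x <- unclass(as.matrix(table))
  cs <- colSums(x)
  assert_that(all(cs > 0), "every sample needs positive total abundance")
  counts <- round(sweep(x, 2, depth / cs, "*"))
  counts[x > 0 & counts == 0] <- 1
  storage.mode(counts) <- "integer"
  counts
}

#' Permutation null distribution of Levins' B
#'
#' Builds per-taxon null distributions of Levins' B by permuting the whole
#' table under a cross-taxon null model and recomputing B for every taxon.
#' The default `"quasiswap"` model permutes the table discretized to integer
#' counts with fixed row totals, column totals and fill
#' (`vegan::nullmodel("quasiswap_count")`); a within-row shuffle would leave
#' B unchanged, so only cross-taxon models are offered. `"within_column"`
#' independently shuffles each sample's values across taxa (preserves sample
#' totals only).
#'
#' @param table an [abundance_table()] (TPM).
#' @param n_permutations number of permuted tables (study default 1000).
#' @param seed RNG seed.
#' @param method `"quasiswap"` (default) or `"within_column"`.
#' @param perm_depth integer depth for count discretization under quasiswap.
#' @param ci_level interval level for the returned quantiles (default 0.95).
#' @return List with `null_b` (n_permutations x n_taxa matrix), `null_low`,
#'   `null_high` (type-7 empirical quantiles per taxon), and `excluded`
#'   (ids of all-zero taxa, dropped with a warning).
#' @export
permutation_null <- function(table, n_permutations = 1000L, seed = 1L,
                             method = c("quasiswap", "within_column"),
                             perm_depth = 10000L, ci_level = 0.95) {
  method <- match.arg(method)
  assert_that(n_permutations >= 1, "n_permutations must be >= 1")
  x <- unclass(as.matrix(table))
  excluded <- rownames(x)[rowSums(x) == 0]
  if (length(excluded) > 0) {
    warning(sprintf("excluding %d all-zero taxa from the null", length(excluded)))
    x <- x[rowSums(x) > 0, , drop = FALSE]
  }
  n_taxa <- nrow(x)
  null_b <- matrix(NA_real_, n_permutations, n_taxa,
                   dimnames = list(NULL, rownames(x)))
  b_of_rows <- function(m) {
    rs <- rowSums(m)
    # a within-column shuffle can zero out a row; B is undefined there
    b <- rep(NA_real_, nrow(m))
    ok <- rs > 0
    b[ok] <- 1 / rowSums((m[ok, , drop = FALSE] / rs[ok])^2)
    b
  }
  if (method == "quasiswap") {
    counts <- discretize_counts(x, depth = perm_depth)
    nm <- vegan::nullmodel(counts, "quasiswap_count")
    sims <- stats::simulate(nm, nsim = n_permutations, seed = seed)
    for (k in seq_len(n_permutations)) {
      null_b[k, ] <- b_of_rows(sims[, , k])
    }
  } else {
    set.seed(seed)
    for (k in seq_len(n_permutations)) {
      perm <- apply(x, 2, sample)
      null_b[k, ] <- b_of_rows(perm)
    }
  }
  alpha <- (1 - ci_level) / 2
  list(null_b = null_b,
       null_low = apply(null_b, 2, stats::quantile, probs = alpha, type = 7,
                        na.rm = TRUE),
       null_high = apply(null_b, 2, stats::quantile, probs = 1 - alpha,
                         type = 7, na.rm = TRUE),
       excluded = excluded)
}

#' Classify one taxon from its observed B and null interval
#'
#' Generalist if B exceeds the upper bound, specialist if below the lower
#' bound, uncategorized otherwise.
#'
#' @param observed_b observed Levins' B.
#' @param null_quantiles length-2 numeric `(low, high)`.
#' @return `"generalist"`, `"specialist"` or `"uncategorized"`.
#' @export
classify <- function(observed_b, null_quantiles) {
  low <- null_quantiles[[1]]; high <- null_quantiles[[2]]
  assert_that(low <= high, "null interval must satisfy low <= high")
  if (observed_b > high) "generalist"
  else if (observed_b < low) "specialist"
  else "uncategorized"
}

#' Niche-breadth classification of every taxon in a table
#'
#' Computes Levins' B per taxon, builds the permutation null via
#' [permutation_null()], and labels each taxon generalist / specialist /
#' uncategorized against the null interval. Taxa detected in fewer than two
#' samples are classified (B near 1) but flagged `low_occupancy`.
#'
#' @inheritParams permutation_null
#' @return data.frame with taxon_id, levins_b, null_low, null_high,
#'   n_permutations, class, mean_abundance, occupancy, low_occupancy.
#' @export
classify_niche <- function(table, n_permutations = 1000L, seed = 1L,
                           method = c("quasiswap", "within_column"),
                           perm_depth = 10000L, ci_level = 0.95) {
  method <- match.arg(method)
  x <- unclass(as.matrix(table))
  keep <- rowSums(x) > 0
  nullres <- permutation_null(table, n_permutations, seed, method,
                              perm_depth, ci_level)
  xk <- x[keep, , drop = FALSE]
  b <- apply(xk, 1, levins_index)
  cls <- vapply(seq_along(b), function(i) {
    classify(b[i], c(nullres$null_low[i], nullres$null_high[i]))
  }, character(1))
  occ <- rowSums(xk > 0)
  data.frame(
    taxon_id = rownames(xk),
    levins_b = unname(b),
    null_low = unname(nullres$null_low),
    null_high = unname(nullres$null_high),
    n_permutations = n_permutations,
    class = cls,
    mean_abundance = unname(rowMeans(xk)),
    occupancy = unname(occ),
    low_occupancy = unname(occ < 2),
    stringsAsFactors = FALSE
  )
}

# extract one rank from GTDB-style taxonomy strings ("d__...;p__...;...")
parse_rank <- function(taxonomy, prefix) {
  out <- rep("unclassified", length(taxonomy))
  hit <- regmatches(taxonomy, regexpr(paste0(prefix, "__[^;]*"), taxonomy))
  has <- grepl(paste0(prefix, "__"), taxonomy)
  val <- sub(paste0("^", prefix, "__"), "", unlist(regmatches(
    taxonomy, regexpr(paste0(prefix, "__[^;]*"), taxonomy))))
  out[has] <- ifelse(nzchar(val), val, "unclassified")
  out[is.na(taxonomy)] <- "unclassified"
  out
}

#' Class composition summaries by taxonomy and region
#'
#' Contingency tables of niche class against phylum, genus, and (from the
#' abundance table and sample metadata) detection counts per region.
#'
#' @param classes output of [classify_niche()].
#' @param genomes genome metadata data.frame with `genome_id`, `taxonomy`.
#' @param table optional [abundance_table()] for region detection counts.
#' @param samples optional sample metadata with `sample_id`, `region`.
#' @return list of data.frames: `by_phylum`, `by_genus`, optionally
#'   `by_region` (class x region detected-taxon counts).
#' @export
class_composition_summary <- function(classes, genomes, table = NULL,
                                      samples = NULL) {
  if (nrow(classes) == 0) {
    empty <- data.frame(class = character(0), rank = character(0),
                        n = integer(0))
    return(list(by_phylum = empty, by_genus = empty))
  }
  tax <- genomes$taxonomy[match(classes$taxon_id, genomes$genome_id)]
  phylum <- parse_rank(tax, "p")
  genus <- parse_rank(tax, "g")
  tab_df <- function(rank_vec) {
    tt <- table(class = classes$class, rank = rank_vec)
    df <- as.data.frame(tt, stringsAsFactors = FALSE)
    names(df) <- c("class", "rank", "n")
    df[df$n > 0, , drop = FALSE]
  }
  out <- list(by_phylum = tab_df(phylum), by_genus = tab_df(genus))
  if (!is.null(table) && !is.null(samples)) {
    x <- unclass(as.matrix(table))[classes$taxon_id, , drop = FALSE]
    region <- samples$region[match(colnames(x), samples$sample_id)]
    regions <- sort(unique(region))
    rows <- lapply(regions, function(r) {
      detected <- rowSums(x[, region == r, drop = FALSE] > 0) > 0
      data.frame(region = r,
                 class = classes$class[detected],
                 stringsAsFactors = FALSE)
    })
    rr <- do.call(rbind, rows)
    tt <- as.data.frame(table(class = rr$class, region = rr$region),
                        stringsAsFactors = FALSE)
    names(tt) <- c("class", "region", "n")
    out$by_region <- tt
  }
  out
}
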