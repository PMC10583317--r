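#' Hypergeometric pathway over-representation test
#'
#' For each pathway, `p = P(X >= k)` under Hypergeom(N universe KOs, K
#' pathway KOs, n module KOs drawn); q-values are Benjamini-Hochberg across
#' pathways within the module. KOs without any pathway annotation count as
#' outside every pathway.
#'
#' @param module_kos character vector of the module's KO ids.
#' @param pathway_map data.frame (ko_id, pathway_id, pathway_name).
#' @param universe character vector of all KOs the network was built on.
#' @return data.frame (module rows sorted by p): pathway_id, pathway_name,
#'   k, K, n, N, p_value, q_value.
#' @export
hypergeometric_enrichment <- function(module_kos, pathway_map, universe) {
  assert_that(all(module_kos %in% universe),
              "module KOs must be a subset of the universe")
  if (length(module_kos) == 0) {
    return(data.frame(pathway_id = character(0), pathway_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  }
  pm <- pathway_map[pathway_map$ko_id %in% universe, , drop = FALSE]
  paths <- unique(pm[, c("pathway_id", "pathway_name")])
  N <- length(universe); n <- length(module_kos)
  out <- paths
  out$k <- NA_integer_; out$K <- NA_integer_
  out$n <- n; out$N <- N; out$p_value <- NA_real_
  for (i in seq_len(nrow(paths))) {
    kos_in_path <- unique(pm$ko_id[pm$pathway_id == paths$pathway_id[i]])
    K <- length(kos_in_path)
    k <- length(intersect(module_kos, kos_in_path))
    out$k[i] <- k; out$K[i] <- K
    out$p_value[i] <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select hub genes in the focal modules
#'
#' The focal modules are the strongest positively and strongest negatively
#' radiation-correlated modules. Within each, KOs must pass both thresholds
#' (kME with their own module above `kme_threshold`, absolute radiation
#' correlation above `trait_cor_threshold`) and be annotated to at least one
#' pathway that is both enriched in the module (q below `enrich_q`) and on
#' the configured pathway whitelist.
#'
#' @param kme features x modules kME matrix.
#' @param module_of named character vector, feature -> module label.
#' @param trait_r named numeric vector of per-KO radiation correlations.
#' @param trait_corr output of [module_trait_correlation()] (radiation rows
#'   used to pick focal modules).
#' @param pathway_map data.frame (ko_id, pathway_id, pathway_name).
#' @param universe KO universe for enrichment.
#' @param whitelist pathway names eligible for hub membership.
#' @param kme_threshold,trait_cor_threshold study defaults 0.9 and 0.8.
#' @param enrich_q enrichment q-value cutoff (default 0.05).
#' @return data.frame: ko_id, module, kme, trait_r, pathways.
#' @export
select_hub_genes <- function(kme, module_of, trait_r, trait_corr,
                             pathway_map, universe,
                             whitelist = run_config()$hub_pathways,
                             kme_threshold = 0.9, trait_cor_threshold = 0.8,
                             enrich_q = 0.05) {
  rad <- trait_corr[trait_corr$covariate == "radiation", , drop = FALSE]
  rad <- rad[rad$module != "grey", , drop = FALSE]
  assert_that(nrow(rad) >= 1, "no module-radiation correlations available")
  pos <- rad$module[rad$pearson_r > 0]
  neg <- rad$module[rad$pearson_r < 0]
  focal <- c(
    if (length(pos)) pos[which.max(rad$pearson_r[rad$pearson_r > 0])],
    if (length(neg)) neg[which.min(rad$pearson_r[rad$pearson_r < 0])]
  )
  hits <- list()
  for (m in focal) {
    members <- names(module_of)[module_of == m]
    enr <- hypergeometric_enrichment(members, pathway_map, universe)
    ok_paths <- enr$pathway_name[enr$q_value <= enrich_q &
                                 enr$pathway_name %in% whitelist]
    if (length(ok_paths) == 0) next
    cand <- members[!is.na(kme[members, m]) &
                    kme[members, m] > kme_threshold &
                    abs(trait_r[members]) > trait_cor_threshold]
    if (length(cand) == 0) next
    pm <- pathway_map[pathway_map$pathway_name %in% ok_paths, , drop = FALSE]
    cand <- cand[cand %in% pm$ko_id]
    if (length(cand) == 0) next
    hits[[m]] <- data.frame(
      ko_id = cand, module = m,
      kme = kme[cand, m], trait_r = trait_r[cand],
      pathways = vapply(cand, function(k) {
        paste(sort(unique(pm$pathway_name[pm$ko_id == k])), collapse = ";")
      }, character(1)),
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0) {
    return(data.frame(ko_id = character(0), module = character(0),
                      kme = numeric(0), trait_r = numeric(0),
                      pathways = character(0)))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Hub co-occurrence subnetwork with betweenness centrality
#'
#' Builds the undirected graph whose edges join selected KOs with
#' `|r| >= edge_threshold` and computes exact betweenness centrality
#' (unnormalized, unweighted shortest paths).
#'
#' @param selected_kos character vector of KO ids (>= 2).
#' @param correlation correlation matrix covering the selected KOs.
#' @param edge_threshold absolute correlation defining an edge (default 0.6).
#' @return list: `edges` (from, to, r), `betweenness` (named vector).
#' @export
hub_subnetwork <- function(selected_kos, correlation, edge_threshold = 0.6) {
  assert_that(length(selected_kos) >= 2, "need at least 2 selected KOs")
  r <- correlation[selected_kos, selected_kos, drop = FALSE]
  adj <- abs(r) >= edge_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ew <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = selected_kos[ew[, 1]], to = selected_kos[ew[, 2]],
                      r = r[ew], stringsAsFactors = FALSE)
  if (nrow(edges) == 0) warning("hub subnetwork has no edges")
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  list(edges = edges, betweenness = stats::setNames(as.numeric(btw),
                                                    selected_kos))
}

#' Map hub KOs onto genomes
#'
#' Presence means the hub KO appears at least once in a genome's annotation.
#'
#' @param hub_kos character vector of hub KO ids.
#' @param annotations data.frame (genome_id, ko_id, copy_count).
#' @param genomes optional metadata for per-phylum tallies.
#' @return list: `presence` (genomes x hubs logical matrix), `counts`
#'   (per-genome hub count), `fraction_with_hub`, optionally `by_phylum`.
#' @export
map_hubs_to_genomes <- function(hub_kos, annotations, genomes = NULL) {
  gids <- sort(unique(annotations$genome_id))
  presence <- matrix(FALSE, length(gids), length(hub_kos),
                     dimnames = list(gids, hub_kos))
  sub <- annotations[annotations$ko_id %in% hub_kos, , drop = FALSE]
  if (nrow(sub) > 0) {
    presence[cbind(match(sub$genome_id, gids), match(sub$ko_id, hub_kos))] <- TRUE
  }
  counts <- rowSums(presence)
  out <- list(presence = presence, counts = counts,
              fraction_with_hub = mean(counts > 0))
  if (!is.null(genomes)) {
    phylum <- parse_rank(
      genomes$taxonomy[match(gids, genomes$genome_id)], "p")
    tt <- as.data.frame(table(phylum = phylum, has_hub = counts > 0),
                        stringsAsFactors = FALSE)
    names(tt) <- c("phylum", "has_hub", "n")
    out$by_phylum <- tt
  }
  out
}

#' Contrast radiation sensitivity between hub-carrying and hub-free genomes
#'
#' Two-sided Wilcoxon rank-sum test on the absolute per-taxon Spearman
#' correlation with radiation, split by hub presence (exact enumeration when
#' both groups have at most 10 members).
#'
#' @param presence_counts named per-genome hub counts from
#'   [map_hubs_to_genomes()].
#' @param taxon_corr output of `taxon_trait_spearman()` (taxon_id,
#'   spearman_rho).
#' @return data.frame: n_with, n_without, statistic, p, median_with,
#'   median_without.
#' @export
hub_sensitivity_contrast <- function(presence_counts, taxon_corr) {
  rho <- abs(taxon_corr$spearman_rho[match(names(presence_counts),
                                           taxon_corr$taxon_id)])
  ok <- !is.na(rho)
  rho <- rho[ok]; has <- presence_counts[ok] > 0
  x <- rho[has]; y <- rho[!has]
  assert_that(length(x) >= 1 && length(y) >= 1,
              "both presence groups must be nonempty")
  if (length(x) <= 10 && length(y) <= 10) {
    res <- wilcox_exact_enum(x, y)
    u <- res$statistic; p <- res$p_value
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    u <- unname(wt$statistic); p <- wt$p.value
  }
  data.frame(n_with = length(x), n_without = length(y), statistic = u, p = p,
             median_with = stats::median(x), median_without = stats::median(y))
}
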