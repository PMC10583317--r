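#' Construct an abundance table (features x samples, TPM units)
#'
#' The basic container for SGB and KO abundance matrices: a nonnegative
#' numeric matrix with unique feature rownames and unique sample colnames.
#' Sample columns are canonicalized to sorted sample id order so results do
#' not depend on input column order.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids,sample_ids optional identifier vectors; default taken
#'   from dimnames.
#' @return An `abundance_table` (a validated matrix subclass).
#' @export
abundance_table <- function(values, feature_ids = rownames(values),
                            sample_ids = colnames(values)) {
  values <- as.matrix(values)
  assert_that(is.numeric(values), "abundance values must be numeric")
  assert_that(!is.null(feature_ids) && !is.null(sample_ids),
              "feature and sample ids are required")
  assert_that(length(feature_ids) == nrow(values) &&
              length(sample_ids) == ncol(values),
              "id lengths must match matrix dimensions")
  assert_that(!anyDuplicated(feature_ids), "duplicate feature ids")
  assert_that(!anyDuplicated(sample_ids), "duplicate sample ids")
  assert_that(!anyNA(values) && all(values >= 0),
              "abundance values must be nonnegative and non-missing")
  dimnames(values) <- list(as.character(feature_ids), as.character(sample_ids))
  ord <- order(colnames(values))
  values <- values[, ord, drop = FALSE]
  class(values) <- c("abundance_table", class(values))
  values
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d features x %d samples (TPM)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

input_schemas <- list(
  sgb_abundance = NULL, # matrix-shaped, handled specially
  ko_abundance  = NULL,
  annotations   = c("genome_id", "ko_id", "copy_count"),
  genomes       = c("genome_id", "est_genome_size_bp", "gc_fraction",
                    "completeness_pct", "contamination_pct", "taxonomy"),
  samples       = c("sample_id", "site", "region", "latitude", "longitude"),
  meteo         = c("sample_id", "radiation", "temperature", "windspeed",
                    "precipitation", "evaporation"),
  pathways      = c("ko_id", "pathway_id", "pathway_name")
)

#' Read a typed input table
#'
#' All inputs are tab-separated with a header row. Matrix schemas
#' (`sgb_abundance`, `ko_abundance`) expect the first column to hold feature
#' ids and the remaining columns one sample each; the result is an
#' [abundance_table()]. Frame schemas are validated against their required
#' columns.
#'
#' @param path file path to a TSV.
#' @param schema one of `"sgb_abundance"`, `"ko_abundance"`, `"annotations"`,
#'   `"genomes"`, `"samples"`, `"meteo"`, `"pathways"`.
#' @param radiation_unit for `schema = "meteo"`: `"MJ"` (default, values kept
#'   as MJ/m^2) or `"J"` (values divided by 1e6 on read).
#' @return An `abundance_table` or a `data.frame`, validated.
#' @export
read_table <- function(path, schema, radiation_unit = c("MJ", "J")) {
  schema <- match.arg(schema, names(input_schemas))
  radiation_unit <- match.arg(radiation_unit)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (schema %in% c("sgb_abundance", "ko_abundance")) {
    assert_that(ncol(df) >= 2, "abundance table needs id column plus samples")
    ids <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- ids
    tab <- abundance_table(mat)
    message(sprintf("read %s: %d features x %d samples", schema,
                    nrow(tab), ncol(tab)))
    return(tab)
  }
  required <- input_schemas[[schema]]
  missing <- setdiff(required, names(df))
  assert_that(length(missing) == 0,
              sprintf("schema '%s': missing column(s) %s", schema,
                      paste(missing, collapse = ", ")))
  if (schema == "samples") {
    assert_that(all(df$region %in% c("ALP", "ARC", "TP")),
                "region must be one of ALP, ARC, TP")
    assert_that(all(df$latitude >= -90 & df$latitude <= 90),
                "latitude out of [-90, 90]")
    assert_that(all(df$longitude >= -180 & df$longitude <= 180),
                "longitude out of [-180, 180]")
    assert_that(!anyDuplicated(df$sample_id), "duplicate sample ids")
  }
  if (schema == "meteo") {
    assert_that(!anyDuplicated(df$sample_id), "duplicate sample ids")
    if (radiation_unit == "J") df$radiation <- df$radiation / 1e6
    assert_that(all(df$radiation >= 0), "radiation must be nonnegative")
    assert_that(all(df$windspeed >= 0), "windspeed must be nonnegative")
  }
  if (schema == "genomes") {
    assert_that(!anyDuplicated(df$genome_id), "duplicate genome ids")
    assert_that(all(df$completeness_pct >= 0 & df$completeness_pct <= 100),
                "completeness must lie in [0, 100]")
  }
  if (schema == "annotations") {
    assert_that(all(df$copy_count >= 1), "copy_count must be >= 1")
  }
  if ("sample_id" %in% names(df)) df <- df[order(df$sample_id), , drop = FALSE]
  rownames(df) <- NULL
  message(sprintf("read %s: %d rows", schema, nrow(df)))
  df
}

#' Write pipeline products to TSV files
#'
#' Each element of `results` is written as `<name>.tsv` with a header and
#' full double precision (15 significant digits), so a read-back reproduces
#' values to at least 12 significant digits. Matrices are written with their
#' rownames in a leading `id` column.
#'
#' @param results named list of data.frames and/or matrices.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a manifest data.frame (file, rows).
#' @export
write_results <- function(results, out_dir) {
  assert_that(is.list(results) && !is.null(names(results)) &&
              all(nzchar(names(results))), "results must be a named list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), sprintf("cannot create %s", out_dir))
  manifest <- data.frame(file = character(0), rows = integer(0))
  old <- options(digits = 15, scipen = 0)
  on.exit(options(old), add = TRUE)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.matrix(x)) {
      x <- data.frame(id = rownames(x) %||% seq_len(nrow(x)),
                      as.data.frame(unclass(x), check.names = FALSE),
                      check.names = FALSE)
    }
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    # format() at 15 sig digits keeps the round trip within 1e-12
    xf <- x
    for (j in seq_along(xf)) {
      if (is.double(xf[[j]])) xf[[j]] <- formatC(xf[[j]], digits = 15,
                                                 format = "g")
    }
    utils::write.table(xf, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    manifest <- rbind(manifest, data.frame(file = basename(path),
                                           rows = nrow(x)))
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Pipeline configuration
#'
#' Bundles every tunable parameter with the defaults used throughout the
#' analysis. Values mirror the study design: 1000 niche permutations with a
#' 95% interval, 70% KO prevalence filter, minimum module size 50, >75%
#' eigengene similarity merging, soft power 7, hub thresholds kME > 0.9 and
#' |r| > 0.8, envfit with 999 permutations.
#'
#' @param ... overrides for any default listed below.
#' @return A named list with class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    n_permutations      = 1000L,
    ci_level            = 0.95,
    null_model          = "quasiswap",   # or "within_column"
    perm_depth          = 10000L,        # integer depth for count discretization
    prevalence_threshold = 0.70,
    min_module_size     = 50L,
    merge_similarity    = 0.75,
    soft_power          = 7L,            # NULL => choose from fit
    soft_power_grid     = 1:20,
    scale_free_target   = 0.80,
    cut_height_grid     = NULL,          # NULL => scan all merge-height midpoints
    kme_reassign_threshold = 0.7,
    kme_threshold       = 0.9,
    trait_cor_threshold = 0.8,
    edge_threshold      = 0.6,
    hub_pathways        = c("bacterial motility proteins", "biofilm formation",
                            "flagellar assembly",
                            "O-antigen nucleotide sugar biosynthesis",
                            "quorum sensing", "secretion system",
                            "two-component system"),
    envfit_permutations = 999L,
    mrm_permutations    = 999L,
    diffslope_permutations = 999L,
    k_folds             = 10L,
    n_lambda            = 100L,
    lambda_min_ratio    = 1e-4,
    vif_threshold       = 10,
    rng_seed            = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  assert_that(length(unknown) == 0,
              sprintf("unknown config field(s): %s",
                      paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  with(cfg, {
    assert_that(n_permutations >= 1, "n_permutations must be positive")
    assert_that(ci_level > 0 && ci_level < 1, "ci_level must lie in (0,1)")
    assert_that(prevalence_threshold > 0 && prevalence_threshold <= 1,
                "prevalence_threshold must lie in (0,1]")
    assert_that(min_module_size >= 2, "min_module_size must be >= 2")
    assert_that(merge_similarity > 0 && merge_similarity < 1,
                "merge_similarity must lie in (0,1)")
    assert_that(kme_threshold > 0 && kme_threshold < 1,
                "kme_threshold must lie in (0,1)")
    assert_that(trait_cor_threshold > 0 && trait_cor_threshold < 1,
                "trait_cor_threshold must lie in (0,1)")
  })
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are `run_config()` fields.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  assert_that(requireNamespace("yaml", quietly = TRUE),
              "the yaml package is required to load config files")
  do.call(run_config, yaml::yaml.load_file(path))
}
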