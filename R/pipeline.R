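# Pipeline orchestration: filter -> occupancy/core -> neutral -> diversity ->
# exposome, from a single config (R list or YAML file), with a run manifest.

config_hash <- function(x) {
  # stable polynomial hash of the serialized config, for the run manifest
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483629
  sprintf("%08x", h)
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

load_inputs <- function(config) {
  table <- if (inherits(config$table, "abundance_table")) config$table
           else read_abundance_table(config$table_path,
                                     format = config$table_format %||% "tsv")
  metadata <- if (is.data.frame(config$metadata)) config$metadata
              else if (!is.null(config$metadata_path)) read_metadata(config$metadata_path)
              else NULL
  taxonomy <- if (is.data.frame(config$taxonomy)) config$taxonomy
              else if (!is.null(config$taxonomy_path)) read_taxonomy(config$taxonomy_path)
              else NULL
  list(table = table, metadata = metadata, taxonomy = taxonomy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_schemes <- function(schemes, metadata) {
  for (sc in schemes) {
    grouping <- sc$grouping %||% "none"
    if (grouping != "none") {
      if (is.null(metadata)) stop("scheme '", sc$name, "' needs metadata")
      if (!grouping %in% names(metadata))
        stop("scheme '", sc$name, "' references missing covariate: ", grouping)
    }
    if (!is.null(sc$subset)) {
      bad <- setdiff(names(sc$subset), names(metadata))
      if (length(bad))
        stop("scheme '", sc$name, "' subsets on missing covariate: ",
             paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

subset_samples <- function(table, metadata, subset) {
  if (is.null(subset)) return(table)
  keep <- rep(TRUE, nrow(table))
  for (cv in names(subset)) {
    keep <- keep & metadata[sample_ids(table), cv] %in% subset[[cv]]
  }
  abundance_table(as_matrix(table)[keep, , drop = FALSE])
}

#' Run the core-microbiome pipeline
#'
#' Pre-processes the table, then for each configured occupancy scheme ranks
#' taxa, builds the Bray-Curtis contribution curve, applies both stopping
#' rules, fits the neutral model with 95% envelope and partitions the taxa.
#' A scheme is a list with `name`, `grouping` (covariate or "none") and
#' optional `subset` (named list covariate -> retained level(s)); the default
#' schemes mirror a pooled analysis plus province-specific occupancy within
#' each gender and gender-specific occupancy overall.
#'
#' @param config R list or YAML path with entries `table`/`table_path`,
#'   optional `metadata`/`metadata_path`, `taxonomy`/`taxonomy_path`,
#'   `schemes`, `min_reads`, `contaminant_threshold`, `max_rank`, `seed`,
#'   `out_dir`
#' @return list of class `core_pipeline_result`: per-scheme list with
#'   `core` ([select_core()] result), `neutral` (partitioned fit over core
#'   taxa context), `phyla` (if taxonomy given), plus `table` (post-filter)
#'   and `manifest`
#' @export
run_core_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  inputs <- load_inputs(config)
  metadata <- inputs$metadata
  schemes <- config$schemes %||% list(list(name = "pooled", grouping = "none"))
  validate_schemes(schemes, metadata)
  if (!is.null(config$seed)) set.seed(config$seed)

  pre <- preprocess_table(inputs$table, metadata, inputs$taxonomy,
                          contaminant_threshold = config$contaminant_threshold %||% 0.1,
                          min_reads = config$min_reads %||% 2000)
  table <- pre$table

  results <- list()
  for (sc in schemes) {
    tab_s <- subset_samples(table, metadata, sc$subset)
    core <- select_core(tab_s, metadata, sc$grouping %||% "none",
                        max_rank = config$max_rank)
    fit <- partition_taxa(confidence_envelope(fit_migration(tab_s)))
    core_labels <- fit$taxa[fit$taxa$taxon_id %in% core$core_last2pct, ]
    phyla <- if (!is.null(inputs$taxonomy))
      core_phylum_composition(core$core_last2pct, inputs$taxonomy) else NULL
    results[[sc$name]] <- list(core = core, neutral = fit,
                               core_neutral_labels = core_labels,
                               phyla = phyla)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("coreniche")),
    seed = config$seed, config_hash = config_hash(config),
    n_samples = nrow(table), n_taxa = ncol(table),
    filter_report = lapply(pre$report, function(x) if (is.data.frame(x)) nrow(x) else length(x))
  )
  out <- structure(list(schemes = results, table = table,
                        filter_report = pre$report, manifest = manifest),
                   class = "core_pipeline_result")
  if (!is.null(config$out_dir)) write_core_pipeline(out, config$out_dir)
  out
}

write_core_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(result$schemes)) {
    r <- result$schemes[[nm]]
    rk <- r$core$ranking
    rk$in_core_last2pct <- rk$taxon_id %in% r$core$core_last2pct
    rk$in_core_elbow <- rk$taxon_id %in% r$core$core_elbow
    utils::write.table(rk, file.path(out_dir, paste0("core_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(r$neutral$taxa,
                       file.path(out_dir, paste0("neutral_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run per-covariate diversity and PERMANOVA analyses
#'
#' @param table an [abundance_table()]
#' @param metadata metadata data.frame
#' @param covariates covariate names to test one at a time
#' @param n_permutations permutations per test
#' @param seed RNG seed for the permutations
#' @return list with `alpha` (per-sample diversity) and `permanova`
#'   (data.frame: covariate, f, r_squared, p_value)
#' @export
run_diversity_pipeline <- function(table, metadata, covariates,
                                   n_permutations = 999, seed = 42) {
  bad <- setdiff(covariates, names(metadata))
  if (length(bad)) stop("missing covariates: ", paste(bad, collapse = ", "))
  D <- bray_curtis_matrix(table)
  rows <- lapply(seq_along(covariates), function(i) {
    g <- metadata[sample_ids(table), covariates[i]]
    ok <- !is.na(g)
    res <- permanova(D[ok, ok], g[ok], n_permutations, seed = seed + i)
    data.frame(covariate = covariates[i], f = res$f,
               r_squared = res$r_squared, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  list(alpha = alpha_diversity(table), permanova = do.call(rbind, rows))
}

#' Run the exposome contingency pipeline
#'
#' Chi-squared tests of every listed covariate against the anchor, Pearson
#' residual maps for the significant pairs, and the strongest-positive-
#' attractor summary per anchor level.
#'
#' @param config R list or YAML path: `metadata`/`metadata_path`, `anchor`
#'   (default "health_status"), `covariates`, `alpha`, `out_dir`
#' @return [attractor_summary()] result plus per-pair IRR tables
#' @export
run_exposome_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  metadata <- if (is.data.frame(config$metadata)) config$metadata
              else read_metadata(config$metadata_path)
  anchor <- config$anchor %||% "health_status"
  if (!anchor %in% names(metadata))
    stop("anchor covariate absent from metadata: ", anchor)
  covariates <- setdiff(config$covariates %||% character(0), anchor)
  if (!length(covariates)) {
    return(list(tests = data.frame(), attractors = data.frame(), irr = list()))
  }
  bad <- setdiff(covariates, names(metadata))
  if (length(bad)) stop("missing covariates: ", paste(bad, collapse = ", "))
  summ <- attractor_summary(metadata, anchor, covariates,
                            alpha = config$alpha %||% 0.05)
  irr <- lapply(stats::setNames(covariates, covariates), function(cv) {
    tab <- covariate_table(metadata, anchor, cv)
    tryCatch(poisson_loglinear_irr(tab), error = function(e) NULL)
  })
  out <- c(summ, list(irr = irr))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(summ$tests, file.path(config$out_dir, "exposome_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ$attractors,
                       file.path(config$out_dir, "exposome_attractors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
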