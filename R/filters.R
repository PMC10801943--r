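# Pre-processing filters applied, in pipeline order: lineage exclusion ->
# prevalence-based contaminant removal -> low-yield sample removal.

#' Remove low-yield samples
#'
#' Drops samples whose total read count falls strictly below `min_reads`
#' (a sample with exactly `min_reads` reads is retained).
#'
#' @param table an [abundance_table()]
#' @param min_reads minimum total reads a sample must have (default 2000)
#' @return list with `table` (filtered), and `removed`: data.frame of removed
#'   sample ids and their depths
#' @export
filter_low_yield_samples <- function(table, min_reads = 2000) {
  stopifnot(min_reads >= 0)
  depths <- sample_depths(table)
  keep <- depths >= min_reads
  if (!any(keep)) stop("all samples fall below min_reads = ", min_reads)
  removed <- data.frame(sample_id = names(depths)[!keep],
                        depth = unname(depths[!keep]),
                        stringsAsFactors = FALSE)
  list(table = abundance_table(as_matrix(table)[keep, , drop = FALSE]),
       removed = removed)
}

#' Remove taxa by taxonomic lineage
#'
#' Removes taxa whose lineage matches any `rank=value` exclusion rule
#' (case-insensitive comparison at the named rank), and optionally taxa that
#' are unassigned at all seven ranks. Typical use excludes organellar
#' sequences (Family = Mitochondria, Order = Chloroplast).
#'
#' @param table an [abundance_table()]
#' @param taxonomy taxonomy data.frame from [read_taxonomy()]
#' @param exclude_terms named character vector, names are ranks and values the
#'   lineage values to exclude, e.g. `c(Family = "Mitochondria", Order = "Chloroplast")`
#' @param drop_fully_unassigned remove taxa with every rank empty?
#' @return list with `table` (filtered) and `removed`: character vector of
#'   removed taxon ids
#' @export
filter_taxa_by_lineage <- function(table, taxonomy,
                                   exclude_terms = c(Family = "Mitochondria",
                                                     Order = "Chloroplast"),
                                   drop_fully_unassigned = TRUE) {
  ranks <- names(taxonomy)
  bad_rank <- setdiff(names(exclude_terms), ranks)
  if (length(bad_rank))
    stop("exclusion rule names unknown rank(s): ", paste(bad_rank, collapse = ", "))
  tids <- taxon_ids(table)
  tax <- taxonomy[match(tids, rownames(taxonomy)), , drop = FALSE]
  drop <- rep(FALSE, length(tids))
  for (i in seq_along(exclude_terms)) {
    rk <- names(exclude_terms)[i]
    vals <- tolower(trimws(tax[[rk]]))
    vals[is.na(vals)] <- ""
    drop <- drop | vals == tolower(exclude_terms[[i]])
  }
  if (drop_fully_unassigned) {
    lin <- as.matrix(tax)
    lin[is.na(lin)] <- ""
    drop <- drop | apply(lin == "", 1, all)
  }
  list(table = abundance_table(as_matrix(table)[, !drop, drop = FALSE]),
       removed = tids[drop])
}

#' Flag likely contaminants from negative-control prevalence
#'
#' Implements a prevalence-method contaminant screen: for each taxon, the 2x2
#' presence/absence table of (detected vs not) x (negative control vs true
#' sample) is scored with a one-sided exact hypergeometric test — the
#' probability, under independence with fixed margins, that the taxon is at
#' least as prevalent in negative controls as observed. Taxa scoring below
#' `threshold` are flagged. Detection means count > 0 throughout the package.
#'
#' @param table an [abundance_table()]
#' @param metadata metadata data.frame with logical `is_negative_control`
#'   (see [read_metadata()]); rownames must cover the table's samples
#' @param threshold flag taxa with score strictly below this probability
#'   (default 0.1, the screening method's conventional default)
#' @return data.frame (one row per taxon) with columns `taxon_id`,
#'   `prevalence_controls`, `prevalence_samples`, `score`, `flagged`
#' @export
identify_contaminants_prevalence <- function(table, metadata, threshold = 0.1) {
  ids <- sample_ids(table)
  missing <- setdiff(ids, rownames(metadata))
  if (length(missing))
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  is_nc <- metadata[ids, "is_negative_control"]
  n_c <- sum(is_nc)
  n_s <- sum(!is_nc)
  if (n_c < 1)
    stop("no negative-control samples present; skip the contaminant stage")
  if (n_s < 1) stop("no true samples present")
  present <- as_matrix(table) > 0
  k_c <- colSums(present[is_nc, , drop = FALSE])
  k_s <- colSums(present[!is_nc, , drop = FALSE])
  # P(X >= k_c), X ~ Hypergeometric(total detections, non-detections, n_c draws)
  score <- stats::phyper(k_c - 1, m = k_c + k_s,
                         n = (n_c + n_s) - (k_c + k_s),
                         k = n_c, lower.tail = FALSE)
  data.frame(taxon_id = taxon_ids(table),
             prevalence_controls = unname(k_c) / n_c,
             prevalence_samples = unname(k_s) / n_s,
             score = unname(score),
             flagged = unname(score) < threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove listed taxa from a table
#'
#' @param table an [abundance_table()]
#' @param taxa character vector of taxon ids to drop
#' @return filtered `abundance_table`
#' @export
remove_taxa <- function(table, taxa) {
  keep <- !(taxon_ids(table) %in% taxa)
  abundance_table(as_matrix(table)[, keep, drop = FALSE])
}

#' Run the standard pre-processing pipeline
#'
#' Fixed order: lineage exclusion, then contaminant removal against negative
#' controls (skipped with a message when no controls are present), then
#' removal of negative-control samples themselves, then the low-yield sample
#' filter.
#'
#' @inheritParams filter_taxa_by_lineage
#' @inheritParams identify_contaminants_prevalence
#' @inheritParams filter_low_yield_samples
#' @param taxonomy optional taxonomy; lineage filter skipped when `NULL`
#' @return list with `table` and `report` (removed taxa/samples per stage)
#' @export
preprocess_table <- function(table, metadata = NULL, taxonomy = NULL,
                             exclude_terms = c(Family = "Mitochondria",
                                               Order = "Chloroplast"),
                             drop_fully_unassigned = TRUE,
                             contaminant_threshold = 0.1,
                             min_reads = 2000) {
  report <- list()
  if (!is.null(taxonomy)) {
    lf <- filter_taxa_by_lineage(table, taxonomy, exclude_terms,
                                 drop_fully_unassigned)
    table <- lf$table
    report$lineage_removed <- lf$removed
  }
  if (!is.null(metadata) && any(metadata[sample_ids(table), "is_negative_control"])) {
    cont <- identify_contaminants_prevalence(table, metadata,
                                             contaminant_threshold)
    flagged <- cont$taxon_id[cont$flagged]
    table <- remove_taxa(table, flagged)
    report$contaminants_removed <- flagged
    keep <- !metadata[sample_ids(table), "is_negative_control"]
    table <- abundance_table(as_matrix(table)[keep, , drop = FALSE])
  }
  ly <- filter_low_yield_samples(table, min_reads)
  report$low_yield_removed <- ly$removed
  list(table = ly$table, report = report)
}
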