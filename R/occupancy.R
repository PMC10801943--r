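# Occupancy / replicate-consistency ranking of taxa.
#
# Under the pooled ("no site-specific occupancy") model all samples form one
# group and the index reduces to ordinary prevalence; under a site-specific
# model occupancy and full-replicate consistency are computed per group (e.g.
# province of residence, gender) and averaged, which promotes taxa that are
# reliably present within some sites even if rare overall.

#' Per-group occupancy proportions
#'
#' Occupancy of taxon t in group g = fraction of group-g samples in which t is
#' detected (count > 0). With `grouping = "none"` a single group holds all
#' samples.
#'
#' @param table an [abundance_table()]
#' @param metadata metadata data.frame (rownames = sample ids); may be `NULL`
#'   when `grouping = "none"`
#' @param grouping covariate name in `metadata`, or `"none"` for pooled
#'   occupancy
#' @return numeric matrix, taxa x groups, of occupancy proportions in [0, 1]
#' @export
group_occupancy <- function(table, metadata = NULL, grouping = "none") {
  present <- as_matrix(table) > 0
  if (identical(grouping, "none")) {
    groups <- factor(rep("all", nrow(table)))
  } else {
    if (is.null(metadata)) stop("metadata required when grouping != 'none'")
    missing <- setdiff(sample_ids(table), rownames(metadata))
    if (length(missing))
      stop("samples absent from metadata: ", paste(missing, collapse = ", "))
    lab <- metadata[sample_ids(table), grouping]
    if (is.null(lab)) stop("covariate not found in metadata: ", grouping)
    if (anyNA(lab)) stop("missing group labels under covariate: ", grouping)
    groups <- factor(lab)
  }
  if (any(table(groups) == 0)) stop("empty group under covariate: ", grouping)
  occ <- vapply(levels(groups), function(g) {
    colMeans(present[groups == g, , drop = FALSE])
  }, numeric(ncol(table)))
  occ <- matrix(occ, nrow = ncol(table),
                dimnames = list(taxon_ids(table), levels(groups)))
  occ
}

#' Occupancy / replicate-consistency ranking index
#'
#' For G groups, index = (sum of per-group occupancy proportions + number of
#' groups with complete occupancy) / (2 G). The index is 1 exactly when the
#' taxon is detected in every sample of every group. Taxa are ranked by index
#' descending; ties broken by mean relative abundance descending, then taxon
#' id ascending, for determinism.
#'
#' @param occupancies taxa x groups occupancy matrix from [group_occupancy()]
#' @param table the [abundance_table()] the occupancies came from (used for
#'   tie-breaking abundances and overall occupancy)
#' @return data.frame ordered by rank with columns `taxon_id`, `index`,
#'   `sum_freq`, `sum_full`, `overall_occupancy`, `mean_rel_abund`, `rank`
#' @export
ranking_index <- function(occupancies, table) {
  G <- ncol(occupancies)
  if (G < 1) stop("need at least one group")
  sum_freq <- rowSums(occupancies)
  sum_full <- rowSums(occupancies == 1)
  index <- (sum_freq + sum_full) / (2 * G)
  rel <- as_matrix(table) / sample_depths(table)
  mra <- colMeans(rel)[rownames(occupancies)]
  overall <- colMeans(as_matrix(table) > 0)[rownames(occupancies)]
  ord <- order(-index, -mra, rownames(occupancies))
  out <- data.frame(taxon_id = rownames(occupancies),
                    index = unname(index),
                    sum_freq = unname(sum_freq),
                    sum_full = unname(sum_full),
                    overall_occupancy = unname(overall),
                    mean_rel_abund = unname(mra),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank taxa by occupancy and replicate consistency
#'
#' Convenience wrapper: [group_occupancy()] followed by [ranking_index()].
#'
#' @inheritParams group_occupancy
#' @return see [ranking_index()]
#' @export
rank_taxa <- function(table, metadata = NULL, grouping = "none") {
  ranking_index(group_occupancy(table, metadata, grouping), table)
}
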