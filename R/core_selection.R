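# Bray-Curtis contribution curve and the two stopping rules that turn an
# occupancy ranking into a core set.
#
# For a candidate core of the top-k ranked taxa, each sample pair's
# dissimilarity is recomputed with non-core counts zeroed in the numerator
# while the pair's denominator (total abundance of both samples) is kept from
# the full table. The pair's core share is BC_core / BC_all and the curve
# value at rank k is the mean share over pairs. Keeping full-table
# denominators makes the curve non-decreasing in k and equal to 1 at k = P.
# The methods literature writes the same quantity as C = 1 - BC_core/BC_all
# on the similarity scale; both stopping rules depend only on relative changes
# along the curve, which agree under either reading.

#' Bray-Curtis contribution curve over a taxon ranking
#'
#' @param table an [abundance_table()]
#' @param ranking character vector of taxon ids in rank order (e.g.
#'   `rank_taxa(...)$taxon_id`), or a ranking data.frame with a `taxon_id`
#'   column
#' @param max_rank compute the curve up to this rank (default: all taxa)
#' @param relative convert each sample to relative abundances first
#'   (default TRUE; Bray-Curtis on raw counts is confounded by uneven depth)
#' @return numeric vector `curve` of length `max_rank`; `curve[k]` is the mean
#'   over sample pairs of BC_core/BC_all for the top-k core. Identical sample
#'   pairs (BC_all = 0) are excluded from the mean.
#' @export
bc_contribution_curve <- function(table, ranking, max_rank = NULL,
                                  relative = TRUE) {
  if (is.data.frame(ranking)) ranking <- ranking$taxon_id
  if (nrow(table) < 2) stop("need at least 2 samples")
  bad <- setdiff(ranking, taxon_ids(table))
  if (length(bad)) stop("ranking names unknown taxa: ", paste(bad, collapse = ", "))
  if (is.null(max_rank)) max_rank <- length(ranking)
  if (max_rank > ncol(table)) stop("max_rank exceeds number of taxa")

  m <- as_matrix(table)[, ranking, drop = FALSE]
  if (relative) m <- m / rowSums(m)
  n <- nrow(m)
  pairs <- utils::combn(n, 2)
  # denominator per pair: total abundance of both samples (full table)
  tot <- rowSums(m)
  denom <- tot[pairs[1, ]] + tot[pairs[2, ]]
  # per-taxon absolute differences per pair, in rank order
  absdiff <- abs(m[pairs[1, ], , drop = FALSE] - m[pairs[2, ], , drop = FALSE])
  bc_all <- rowSums(absdiff) / denom
  ok <- bc_all > 0
  if (!any(ok)) stop("all sample pairs are identical; Bray-Curtis undefined")
  # cumulative numerator over ranked taxa: BC_core(k) per pair
  cum <- absdiff[ok, seq_len(max_rank), drop = FALSE]
  cum <- t(apply(cum, 1, cumsum))
  if (max_rank == 1) cum <- matrix(cum, ncol = 1)
  share <- (cum / denom[ok]) / bc_all[ok]
  unname(colMeans(share))
}

#' Select the core by the last-2-percent criterion
#'
#' Ranks are added while each one still raises the contribution by at least
#' 2% relative to the previous rank: the core is the prefix 1..K where K is
#' the last rank before the first failure of
#' contribution(k)/contribution(k-1) >= 1.02 (K = 1 if rank 2 already fails).
#' Ranks whose predecessor has zero contribution always qualify, so leading
#' zero-contribution stretches are included up to the first strictly positive
#' value.
#'
#' @param curve numeric contribution curve from [bc_contribution_curve()]
#' @param min_ratio relative-gain threshold (default 1.02)
#' @return list with `k` (core prefix length) and `ratios` (the k-to-(k-1)
#'   gain ratios, Inf where the previous value was 0)
#' @export
select_core_last2pct <- function(curve, min_ratio = 1.02) {
  n <- length(curve)
  if (n == 0) stop("empty contribution curve")
  if (n == 1) return(list(k = 1L, ratios = NA_real_))
  prev <- curve[-n]
  ratios <- ifelse(prev > 0, curve[-1] / prev, Inf)
  fail <- which(ratios < min_ratio)
  k <- if (length(fail)) fail[1] else n
  list(k = as.integer(k), ratios = c(NA_real_, ratios))
}

#' Select the core by the elbow criterion
#'
#' For each interior rank i the curve is split in two and the average rates of
#' change of the parts compared:
#' fo_diff(i) = (curve(i) - curve(1))/(i - 1) - (curve(n) - curve(i))/(n - i).
#' The elbow is the rank maximising this difference (ties resolve to the
#' smallest rank; a perfectly linear curve has fo_diff identically zero and
#' returns the first interior rank) and the core is the prefix 1..elbow.
#'
#' @param curve numeric contribution curve of length >= 3
#' @return list with `k` (elbow rank) and `fo_diff` (the difference at each
#'   interior rank, NA at the endpoints)
#' @export
select_core_elbow <- function(curve) {
  n <- length(curve)
  if (n < 3) stop("elbow criterion needs a curve of length >= 3")
  fo <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    fo[i] <- (curve[i] - curve[1]) / (i - 1) - (curve[n] - curve[i]) / (n - i)
  }
  list(k = which.max(fo), fo_diff = fo)
}

#' Phylum composition of a core set
#'
#' @param core_taxa character vector of core taxon ids
#' @param taxonomy taxonomy data.frame from [read_taxonomy()]
#' @return named integer vector: counts of core taxa per phylum, taxa without
#'   a phylum assignment under `"Unknown"`
#' @export
core_phylum_composition <- function(core_taxa, taxonomy) {
  if (length(core_taxa) == 0) return(integer(0))
  phyla <- taxonomy[match(core_taxa, rownames(taxonomy)), "Phylum"]
  phyla[is.na(phyla) | trimws(phyla) == ""] <- "Unknown"
  tab <- table(phyla)
  out <- as.integer(tab)
  names(out) <- names(tab)
  sort(out, decreasing = TRUE)
}

#' Rank taxa and select the core under a stopping rule
#'
#' Runs the full ranking -> contribution curve -> stopping-rule chain and
#' returns both rules' core sets together with the curve and ranking.
#'
#' @inheritParams group_occupancy
#' @inheritParams bc_contribution_curve
#' @param max_rank highest rank at which to evaluate the contribution curve
#'   (default: all taxa; lowering it bounds runtime on large tables but the
#'   curve must still cover the eventual core)
#' @return list of class `core_selection`: `ranking` (data.frame),
#'   `curve`, `core_last2pct` and `core_elbow` (taxon id vectors),
#'   `k_last2pct`, `k_elbow`, `min_occupancy_last2pct` (minimum overall
#'   occupancy among the last-2-percent core taxa)
#' @export
select_core <- function(table, metadata = NULL, grouping = "none",
                        max_rank = NULL, relative = TRUE) {
  ranking <- rank_taxa(table, metadata, grouping)
  curve <- bc_contribution_curve(table, ranking$taxon_id, max_rank, relative)
  last2 <- select_core_last2pct(curve)
  elbow <- if (length(curve) >= 3) select_core_elbow(curve) else list(k = NA_integer_, fo_diff = NA_real_)
  core_l2 <- ranking$taxon_id[seq_len(last2$k)]
  structure(list(
    ranking = ranking,
    curve = curve,
    grouping = grouping,
    k_last2pct = last2$k,
    k_elbow = elbow$k,
    core_last2pct = core_l2,
    core_elbow = if (is.na(elbow$k)) character(0) else ranking$taxon_id[seq_len(elbow$k)],
    min_occupancy_last2pct = min(ranking$overall_occupancy[seq_len(last2$k)])
  ), class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf("core_selection (grouping: %s)\n", x$grouping))
  cat(sprintf("  last-2%% core: %d taxa (min occupancy %.3f)\n",
              x$k_last2pct, x$min_occupancy_last2pct))
  if (!is.na(x$k_elbow)) cat(sprintf("  elbow core:   %d taxa\n", x$k_elbow))
  invisible(x)
}
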