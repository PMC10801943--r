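# Seeded synthetic-community generator with known ground truth.
#
# The stated world mirrors the study design this package targets: samples
# organised as provinces x gender, read depths log-normal around ~20,000
# clipped to [13,000, 37,000], a log-normal metacommunity sampled through the
# Sloan stationary beta-multinomial model with migration rate m, plus injected
# non-neutral taxa — environment-selected (over-occupied at low abundance) and
# dispersal-limited (restricted to a subset of provinces) — and contaminant
# taxa concentrated in negative-control samples.

#' Synthetic-community configuration
#'
#' Defaults emulate the target study's design: six provinces x two genders,
#' eight samples per cell (96 true samples), log-normal depths with mean
#' ~20,000 clipped to [13,000, 37,000], migration rate m = 0.1, four negative
#' controls carrying a dedicated contaminant taxon set, and a planted
#' questionnaire association between poor health and one diet item.
#'
#' @param n_taxa number of taxa (default 500; the study scale is ~3400 but
#'   500 keeps default-config runs light while preserving the S-shaped
#'   abundance-occupancy cloud)
#' @param provinces site labels
#' @param genders gender labels
#' @param samples_per_cell true samples per province x gender cell
#' @param meanlog,sdlog log-normal metacommunity parameters (sdlog 2 gives a
#'   realistic long-tailed rank-abundance curve)
#' @param m migration rate of the neutral model
#' @param depth_meanlog,depth_sdlog,depth_range per-sample read-depth
#'   log-normal parameters and clipping range
#' @param n_selected number of environment-selected taxa to inject
#' @param selected_presence fraction of samples where selected taxa are forced
#'   present
#' @param n_dispersal_limited number of dispersal-limited taxa to inject
#' @param dl_abundance_quantile metacommunity-abundance quantile assigned to
#'   dispersal-limited taxa (default 0.6: site-endemic taxa in multi-site gut
#'   surveys are medium abundance, not community dominants)
#' @param n_allowed_sites provinces a dispersal-limited taxon is allowed in
#' @param dispersal_boost within-site count multiplier for dispersal-limited
#'   taxa; the default `NULL` uses n_provinces / n_allowed_sites, which
#'   conserves the taxon's overall mean abundance while concentrating it in
#'   its allowed sites
#' @param n_controls negative-control samples
#' @param n_contaminants contaminant taxa (dominant in controls, sporadic in
#'   true samples)
#' @param control_depth read depth of negative controls
#' @param planted_odds_multiplier odds multiplier linking the planted diet
#'   level to poor health (1 = no association)
#' @param seed RNG seed; fully determines the generated data
#' @return list of class `synthetic_config`
#' @export
synthetic_config <- function(n_taxa = 500,
                             provinces = c("Punjab", "Sindh", "Balochistan",
                                           "KPK", "ICT", "AJK"),
                             genders = c("male", "female"),
                             samples_per_cell = 8,
                             meanlog = 0, sdlog = 2,
                             m = 0.1,
                             depth_meanlog = log(20000), depth_sdlog = 0.25,
                             depth_range = c(13000, 37000),
                             n_selected = 20, selected_presence = 0.98,
                             n_dispersal_limited = 20, n_allowed_sites = 2,
                             dl_abundance_quantile = 0.6,
                             dispersal_boost = NULL,
                             n_controls = 4, n_contaminants = 11,
                             control_depth = 5000,
                             planted_odds_multiplier = 5,
                             seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_taxa >= 1, m > 0,
            n_selected + n_dispersal_limited + n_contaminants <= n_taxa,
            n_allowed_sites >= 1, n_allowed_sites <= length(provinces))
  structure(cfg, class = "synthetic_config")
}

#' Draw a log-normal metacommunity abundance vector
#'
#' @param n_taxa number of taxa
#' @param meanlog,sdlog log-normal parameters
#' @return numeric vector summing to 1
#' @export
generate_metacommunity <- function(n_taxa, meanlog = 0, sdlog = 2) {
  x <- stats::rlnorm(n_taxa, meanlog, sdlog)
  x / sum(x)
}

#' Simulate neutral counts under the Sloan stationary model
#'
#' Per sample, each taxon's local relative abundance is drawn from
#' Beta(N m p_i, N m (1 - p_i)) with N the mean depth, the vector renormalised
#' and counts drawn multinomially at the sample's depth, so every sample's
#' counts sum exactly to its depth.
#'
#' @param p metacommunity relative abundances (sum 1)
#' @param m migration rate
#' @param depths per-sample read depths
#' @param sample_ids,taxon_ids identifiers (defaults generated)
#' @return an [abundance_table()]
#' @export
simulate_neutral_counts <- function(p, m, depths,
                                    sample_ids = NULL, taxon_ids = NULL) {
  stopifnot(m > 0, all(depths > 0))
  N <- mean(depths)
  n_taxa <- length(p)
  n_samples <- length(depths)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n_samples))
  if (is.null(taxon_ids)) taxon_ids <- sprintf("ASV_%04d", seq_len(n_taxa))
  counts <- matrix(0, n_samples, n_taxa)
  for (s in seq_len(n_samples)) {
    x <- stats::rbeta(n_taxa, N * m * p, N * m * (1 - p))
    x[!is.finite(x)] <- 0
    if (sum(x) == 0) x <- p
    counts[s, ] <- stats::rmultinom(1, depths[s], x / sum(x))
  }
  abundance_table(counts, sample_ids, taxon_ids)
}

adjust_depth <- function(counts, target) {
  # restore a sample's total to target by adjusting its most abundant taxon,
  # preserving small forced-present counts exactly
  diff <- target - sum(counts)
  if (diff != 0) {
    j <- which.max(counts)
    counts[j] <- max(0, counts[j] + diff)
  }
  counts
}

#' Inject non-neutral taxa into a neutral table
#'
#' Environment-selected taxa are forced present (small positive count) in
#' `selected_presence` of the samples while staying at low mean abundance, so
#' their occupancy sits above the neutral expectation. Dispersal-limited taxa
#' are zeroed outside their allowed provinces and boosted within, putting
#' their occupancy below the expectation at their abundance. Per-sample totals
#' are restored to the original depths.
#'
#' @param table an [abundance_table()] of true samples
#' @param metadata metadata with a `province` column aligned to the table
#' @param config a [synthetic_config()]
#' @param selected_taxa,dispersal_taxa taxon ids to modify
#' @param allowed_sites named list: for each dispersal-limited taxon, the
#'   provinces it is allowed in
#' @return modified `abundance_table`
#' @export
inject_non_neutral_taxa <- function(table, metadata, config,
                                    selected_taxa, dispersal_taxa,
                                    allowed_sites) {
  m <- as_matrix(table)
  depths <- rowSums(m)
  n <- nrow(m)
  prov <- metadata[sample_ids(table), "province"]
  for (t in selected_taxa) {
    present <- stats::runif(n) < config$selected_presence
    need <- present & m[, t] == 0
    m[need, t] <- 1 + stats::rpois(sum(need), 2)
  }
  boost <- config$dispersal_boost %||%
    (length(config$provinces) / config$n_allowed_sites)
  for (t in dispersal_taxa) {
    allow <- allowed_sites[[t]]
    if (length(allow) == 0) stop("empty allowed-site subset for taxon ", t)
    outside <- !(prov %in% allow)
    m[outside, t] <- 0
    inside <- which(!outside)
    m[inside, t] <- round(m[inside, t] * boost)
    # a site-endemic taxon is reliably detected in its home sites
    zero <- inside[m[inside, t] == 0]
    m[zero, t] <- 1 + stats::rpois(length(zero), 2)
  }
  for (s in seq_len(n)) m[s, ] <- adjust_depth(m[s, ], depths[s])
  abundance_table(m, sample_ids(table), taxon_ids(table))
}

#' Generate sample metadata for a synthetic design
#'
#' Builds the province x gender design (plus negative controls), a
#' three-level self-reported health covariate, a planted diet covariate whose
#' one level has its odds multiplied by `planted_odds_multiplier` among
#' poor-health respondents, and an unrelated noise covariate.
#'
#' @param config a [synthetic_config()]
#' @return data.frame: rownames = sample ids; columns province, gender,
#'   health_status, diet_pickle, exercise, is_negative_control
#' @export
generate_metadata <- function(config) {
  cells <- expand.grid(province = config$provinces, gender = config$genders,
                       stringsAsFactors = FALSE)
  province <- rep(cells$province, each = config$samples_per_cell)
  gender <- rep(cells$gender, each = config$samples_per_cell)
  n <- length(province)
  health <- sample(c("excellent", "good", "poor"), n, replace = TRUE,
                   prob = c(0.3, 0.5, 0.2))
  base_odds <- 0.3 / 0.7
  odds <- ifelse(health == "poor", base_odds * config$planted_odds_multiplier,
                 base_odds)
  diet <- ifelse(stats::runif(n) < odds / (1 + odds), "yes", "no")
  exercise <- sample(c("regular", "rare"), n, replace = TRUE)
  ids <- sprintf("S%03d", seq_len(n))
  md <- data.frame(province = province, gender = gender,
                   health_status = health, diet_pickle = diet,
                   exercise = exercise, is_negative_control = FALSE,
                   stringsAsFactors = FALSE, row.names = ids)
  if (config$n_controls > 0) {
    k <- config$n_controls
    nc <- data.frame(province = rep(NA_character_, k), gender = NA_character_,
                     health_status = NA_character_, diet_pickle = NA_character_,
                     exercise = NA_character_, is_negative_control = TRUE,
                     stringsAsFactors = FALSE,
                     row.names = sprintf("NC%02d", seq_len(k)))
    md <- rbind(md, nc)
  }
  md
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Runs the full generator: metadata/design, log-normal metacommunity,
#' neutral counts, non-neutral injection, contaminant-bearing negative
#' controls. Fully deterministic under `config$seed`.
#'
#' @param config a [synthetic_config()]
#' @return list with `table` (all samples incl. controls), `metadata`,
#'   `truth` (data.frame: taxon_id, class in
#'   neutral/selected/dispersal_limited/contaminant), `p` (metacommunity),
#'   `m`, `allowed_sites`, `config`
#' @export
generate_synthetic_dataset <- function(config = synthetic_config()) {
  set.seed(config$seed)
  metadata <- generate_metadata(config)
  true_ids <- rownames(metadata)[!metadata$is_negative_control]

  n_taxa <- config$n_taxa
  taxon_ids <- sprintf("ASV_%04d", seq_len(n_taxa))
  class <- rep("neutral", n_taxa)
  n_inj <- config$n_selected + config$n_dispersal_limited + config$n_contaminants
  inj <- if (n_inj > 0) sample(n_taxa, n_inj) else integer(0)
  sel_idx <- utils::head(inj, config$n_selected)
  dl_idx <- inj[seq_len(config$n_dispersal_limited) + config$n_selected]
  cont_idx <- utils::tail(inj, config$n_contaminants)
  class[sel_idx] <- "selected"
  class[dl_idx] <- "dispersal_limited"
  class[cont_idx] <- "contaminant"

  p <- generate_metacommunity(n_taxa, config$meanlog, config$sdlog)
  # selected taxa live at low metacommunity abundance, dispersal-limited at
  # medium abundance, contaminants near zero
  if (length(sel_idx)) p[sel_idx] <- stats::quantile(p, 0.25)
  if (length(dl_idx)) p[dl_idx] <- stats::quantile(p, config$dl_abundance_quantile)
  if (length(cont_idx)) p[cont_idx] <- min(p[p > 0]) * 0.01
  p <- p / sum(p)

  depths <- round(stats::rlnorm(length(true_ids), config$depth_meanlog,
                                config$depth_sdlog))
  depths <- pmin(pmax(depths, config$depth_range[1]), config$depth_range[2])
  table <- simulate_neutral_counts(p, config$m, depths,
                                   sample_ids = true_ids,
                                   taxon_ids = taxon_ids)

  allowed_sites <- stats::setNames(lapply(seq_along(dl_idx), function(i) {
    sample(config$provinces, config$n_allowed_sites)
  }), taxon_ids[dl_idx])
  table <- inject_non_neutral_taxa(table, metadata, config,
                                   selected_taxa = taxon_ids[sel_idx],
                                   dispersal_taxa = taxon_ids[dl_idx],
                                   allowed_sites = allowed_sites)

  if (config$n_controls > 0) {
    nc_ids <- rownames(metadata)[metadata$is_negative_control]
    ncm <- matrix(0, length(nc_ids), n_taxa)
    for (s in seq_along(nc_ids)) {
      w <- stats::runif(n_taxa) * 1e-4          # faint cross-talk
      w[cont_idx] <- stats::runif(length(cont_idx), 0.5, 1)
      ncm[s, ] <- stats::rmultinom(1, config$control_depth, w / sum(w))
    }
    # contaminants also bleed sporadically into a few true samples
    tm <- as_matrix(table)
    for (t in cont_idx) {
      hit <- stats::runif(nrow(tm)) < 0.05
      tm[hit, t] <- tm[hit, t] + 1 + stats::rpois(sum(hit), 1)
    }
    for (s in seq_len(nrow(tm))) tm[s, ] <- adjust_depth(tm[s, ], depths[s])
    full <- rbind(tm, ncm)
    table <- abundance_table(full, c(rownames(tm), nc_ids), taxon_ids)
  }

  list(table = table,
       metadata = metadata,
       truth = data.frame(taxon_id = taxon_ids, class = class,
                          stringsAsFactors = FALSE),
       p = stats::setNames(p, taxon_ids),
       m = config$m,
       allowed_sites = allowed_sites,
       config = config)
}
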