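# Sloan neutral community model.
#
# At stationarity a taxon with metacommunity relative abundance p has local
# relative abundance X ~ Beta(N*m*p, N*m*(1-p)), where N is the local
# community size (approximated by the mean read depth) and m the migration
# rate. Predicted occupancy is P(X > d) with detection limit d = 1/N. Fitting
# m by least squares to the observed abundance-occupancy cloud, taxa whose
# observed occupancy falls outside a 95% binomial (Wilson) envelope around the
# prediction are called non-neutral: above = selected by the host/environment,
# below = dispersal limited.

#' Sloan-model predicted occupancy
#'
#' @param p metacommunity mean relative abundance(s), in [0, 1]
#' @param N community size (mean reads per sample)
#' @param m migration rate (> 0)
#' @param d detection limit, default 1/N
#' @return probability of detection, P(Beta(Nmp, Nm(1-p)) > d); 0 at p = 0 and
#'   1 at p = 1
#' @export
sloan_predicted_occupancy <- function(p, N, m, d = 1 / N) {
  stopifnot(N > 0, m > 0, d > 0, d < 1)
  out <- stats::pbeta(d, N * m * p, N * m * (1 - p), lower.tail = FALSE)
  out[p <= 0] <- 0
  out[p >= 1] <- 1
  out
}

#' Fit the Sloan neutral model to an abundance table
#'
#' N is the mean sample depth, d = 1/N, and each taxon's p is its mean
#' relative abundance across samples. The migration rate m minimises the sum
#' of squared differences between observed and predicted occupancy over taxa
#' with nonzero occupancy, searched on m in (1e-6, 10] from multiple starts.
#'
#' @param table an [abundance_table()]
#' @param community_size `"mean"` (default) or `"median"` read depth as N
#' @param m_bounds search interval for m
#' @param starts multi-start initial values
#' @return object of class `neutral_fit`: list with `m`, `N`, `d`,
#'   `r_squared`, and `taxa` — a data.frame (taxon_id, p, occupancy,
#'   predicted) over the fitted (nonzero-occupancy) taxa
#' @export
fit_migration <- function(table, community_size = c("mean", "median"),
                          m_bounds = c(1e-6, 10),
                          starts = c(0.01, 0.1, 1)) {
  community_size <- match.arg(community_size)
  if (nrow(table) < 5) stop("need at least 5 samples to fit")
  depths <- sample_depths(table)
  N <- if (community_size == "mean") mean(depths) else stats::median(depths)
  rel <- as_matrix(table) / depths
  p <- colMeans(rel)
  occ <- colMeans(as_matrix(table) > 0)
  keep <- occ > 0 & p > 0 & p < 1
  if (sum(keep) < 10) stop("need at least 10 taxa with nonzero occupancy")
  fit <- fit_migration_occupancy(p[keep], occ[keep], N,
                                 m_bounds = m_bounds, starts = starts)
  fit$n_samples <- nrow(table)
  fit
}

#' Fit the migration rate to an abundance-occupancy cloud
#'
#' The vector-level work-horse behind [fit_migration()]: least-squares fit of
#' the Sloan occupancy curve to paired (p, occupancy) observations.
#'
#' @param p per-taxon mean relative abundances (names become taxon ids)
#' @param occupancy per-taxon observed occupancy in [0, 1]
#' @param N community size (reads per sample)
#' @param d detection limit, default 1/N
#' @inheritParams fit_migration
#' @return a `neutral_fit` (see [fit_migration()])
#' @export
fit_migration_occupancy <- function(p, occupancy, N, d = 1 / N,
                                    m_bounds = c(1e-6, 10),
                                    starts = c(0.01, 0.1, 1)) {
  stopifnot(length(p) == length(occupancy), N > 0)
  sse <- function(log_m) {
    pred <- sloan_predicted_occupancy(p, N, exp(log_m), d)
    sum((occupancy - pred)^2)
  }
  fits <- lapply(starts, function(s) {
    tryCatch(stats::optim(log(s), sse, method = "Brent",
                          lower = log(m_bounds[1]), upper = log(m_bounds[2])),
             error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (!length(fits))
    stop("migration-rate optimisation failed at every start (starts: ",
         paste(starts, collapse = ", "), ")")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  m <- exp(best$par)
  pred <- sloan_predicted_occupancy(p, N, m, d)
  sst <- sum((occupancy - mean(occupancy))^2)
  r2 <- if (sst > 0) 1 - best$value / sst else NA_real_
  ids <- names(p) %||% sprintf("taxon_%d", seq_along(p))
  structure(list(
    m = m, N = N, d = d, r_squared = r2, n_samples = NA_integer_,
    taxa = data.frame(taxon_id = ids, p = unname(p),
                      occupancy = unname(occupancy), predicted = unname(pred),
                      stringsAsFactors = FALSE, row.names = NULL)
  ), class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("neutral_fit: m = %.4f, N = %.0f, R^2 = %.3f over %d taxa\n",
              x$m, x$N, x$r_squared, nrow(x$taxa)))
  invisible(x)
}

#' Wilson score interval
#'
#' @param p_hat proportion(s)
#' @param n number of trials
#' @param confidence confidence level (default 0.95); 0 collapses both bounds
#'   onto `p_hat`
#' @return matrix with columns `lower`, `upper`
#' @export
wilson_interval <- function(p_hat, n, confidence = 0.95) {
  z <- if (confidence <= 0) 0 else stats::qnorm(1 - (1 - confidence) / 2)
  denom <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Confidence envelope around predicted occupancy
#'
#' Wilson score interval around each taxon's predicted occupancy treated as a
#' binomial proportion with n = number of samples.
#'
#' @param fit a `neutral_fit` from [fit_migration()]
#' @param confidence confidence level (default 0.95)
#' @param n_samples number of binomial trials; defaults to the fit's sample
#'   count
#' @return the fit with `lower`/`upper` columns added to `$taxa`
#' @export
confidence_envelope <- function(fit, confidence = 0.95, n_samples = fit$n_samples) {
  ci <- wilson_interval(fit$taxa$predicted, n_samples, confidence)
  fit$taxa$lower <- ci[, "lower"]
  fit$taxa$upper <- ci[, "upper"]
  fit$confidence <- confidence
  fit
}

#' Partition taxa against the neutral envelope
#'
#' Labels each fitted taxon `above` (observed occupancy strictly above the
#' upper envelope: selected by the host/environment), `below` (strictly below
#' the lower envelope: dispersal limited) or `neutral`. Boundary equality
#' resolves to `neutral` — conservative with respect to claiming selection.
#'
#' @param fit a `neutral_fit` with envelope (see [confidence_envelope()]);
#'   the envelope is added at 95% if absent
#' @return the fit with a `label` column added to `$taxa`
#' @export
partition_taxa <- function(fit) {
  if (is.null(fit$taxa$lower)) fit <- confidence_envelope(fit)
  lab <- rep("neutral", nrow(fit$taxa))
  lab[fit$taxa$occupancy > fit$taxa$upper] <- "above"
  lab[fit$taxa$occupancy < fit$taxa$lower] <- "below"
  fit$taxa$label <- lab
  fit
}
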