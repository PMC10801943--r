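# Chi-squared independence testing, Pearson-residual attraction/repulsion
# maps and Poisson log-linear incidence-rate ratios for pairs of categorical
# questionnaire covariates.

check_contingency <- function(table) {
  m <- as.matrix(table)
  if (length(dim(m)) != 2) stop("contingency table must be 2-dimensional")
  if (any(m < 0) || any(m != round(m))) stop("cells must be non-negative integers")
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 levels per margin")
  if (sum(m) == 0) stop("zero grand total")
  rz <- rowSums(m) == 0
  cz <- colSums(m) == 0
  if (any(rz)) stop("zero row margin for level: ",
                    paste(rownames(m)[rz], collapse = ", "))
  if (any(cz)) stop("zero column margin for level: ",
                    paste(colnames(m)[cz], collapse = ", "))
  m
}

expected_cells <- function(m) outer(rowSums(m), colSums(m)) / sum(m)

#' Chi-squared test of independence
#'
#' Pearson chi-squared statistic with expected cells E = row x col / total;
#' Yates continuity correction is applied to 2x2 tables (the convention of
#' the standard test), never to larger ones. Warns when any expected cell is
#' below 5.
#'
#' @param table 2-D table/matrix of non-negative integer frequencies with at
#'   least two levels on each margin
#' @return list: `statistic`, `df`, `p_value`, `expected`, `yates` (logical)
#' @export
chi2_independence <- function(table) {
  m <- check_contingency(table)
  E <- expected_cells(m)
  if (any(E < 5))
    warning("expected cell count below 5; chi-squared approximation may be poor")
  yates <- all(dim(m) == c(2, 2))
  dev <- abs(m - E)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = E, yates = yates)
}

#' Pearson residuals of a contingency table
#'
#' r_ij = (O_ij - E_ij) / sqrt(E_ij), without continuity correction. Positive
#' residuals mark attraction between the row and column levels, negative
#' residuals repulsion; the squared residuals sum to the uncorrected
#' chi-squared statistic.
#'
#' @inheritParams chi2_independence
#' @return numeric matrix of residuals, same dimnames as the input
#' @export
pearson_residuals <- function(table) {
  m <- check_contingency(table)
  E <- expected_cells(m)
  (m - E) / sqrt(E)
}

#' Incidence-rate ratios from a main-effects Poisson log-linear model
#'
#' Fits Freq ~ A + B by Poisson GLM with log link on the cell frequencies of
#' a two-way table and exponentiates the coefficients. The reference level of
#' each factor is its first declared level; the main-effects model fits the
#' independence cells row x col / total exactly, so each IRR is the ratio of
#' that level's margin to the reference level's margin.
#'
#' @inheritParams chi2_independence
#' @param conf_level confidence level for Wald intervals (default 0.95)
#' @return data.frame: factor ("A" = rows, "B" = columns), level, irr,
#'   lower, upper
#' @export
poisson_loglinear_irr <- function(table, conf_level = 0.95) {
  m <- check_contingency(table)
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  df <- expand.grid(A = factor(rownames(m), levels = rownames(m)),
                    B = factor(colnames(m), levels = colnames(m)))
  df$Freq <- as.vector(m)
  fit <- stats::glm(Freq ~ A + B, family = stats::poisson(), data = df)
  if (!fit$converged) stop("Poisson log-linear model did not converge")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  co <- summary(fit)$coefficients
  keep <- grep("^(A|B)", rownames(co))
  est <- co[keep, "Estimate"]
  se <- co[keep, "Std. Error"]
  nm <- rownames(co)[keep]
  data.frame(
    factor = substr(nm, 1, 1),
    level = substring(nm, 2),
    irr = exp(est),
    lower = exp(est - z * se),
    upper = exp(est + z * se),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Cross-tabulate two metadata covariates
#'
#' @param metadata metadata data.frame (see [read_metadata()])
#' @param a,b covariate names
#' @return integer contingency table (levels of `a` x levels of `b`),
#'   negative-control samples excluded
#' @export
covariate_table <- function(metadata, a, b) {
  for (v in c(a, b)) if (!v %in% names(metadata))
    stop("covariate not found in metadata: ", v)
  md <- metadata[!metadata$is_negative_control, , drop = FALSE]
  ok <- !is.na(md[[a]]) & !is.na(md[[b]])
  table(md[[a]][ok], md[[b]][ok], dnn = c(a, b))
}

#' Strongest positive attractors of an anchor covariate
#'
#' Tests the anchor covariate against each candidate covariate; among pairs
#' with a significant chi-squared test (p < alpha) and for each anchor level,
#' reports the covariate/level whose Pearson residual with that anchor level
#' is largest and positive.
#'
#' @param metadata metadata data.frame
#' @param anchor anchor covariate name (rows of each table)
#' @param covariates candidate covariate names to test against the anchor
#' @param alpha significance gate (default 0.05); no multiplicity correction
#'   unless `adjust = "BH"`
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg across
#'   the tested pairs
#' @return list with `tests` (per-pair data.frame: covariate, statistic, df,
#'   p_value, significant) and `attractors` (per anchor-level data.frame:
#'   anchor_level, covariate, level, residual), empty when nothing is
#'   significant
#' @export
attractor_summary <- function(metadata, anchor, covariates, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  tests <- data.frame(covariate = covariates, statistic = NA_real_,
                      df = NA_integer_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
  resids <- list()
  for (i in seq_along(covariates)) {
    tab <- covariate_table(metadata, anchor, covariates[i])
    res <- suppressWarnings(chi2_independence(tab))
    tests$statistic[i] <- res$statistic
    tests$df[i] <- res$df
    tests$p_value[i] <- res$p_value
    resids[[covariates[i]]] <- pearson_residuals(tab)
  }
  p_adj <- if (adjust == "BH") stats::p.adjust(tests$p_value, "BH") else tests$p_value
  tests$significant <- p_adj < alpha

  rows <- list()
  sig <- covariates[tests$significant]
  if (length(sig)) {
    anchor_levels <- rownames(resids[[sig[1]]])
    for (lev in anchor_levels) {
      best <- NULL
      for (cv in sig) {
        r <- resids[[cv]][lev, ]
        j <- which.max(r)
        if (r[j] > 0 && (is.null(best) || r[j] > best$residual)) {
          best <- data.frame(anchor_level = lev, covariate = cv,
                             level = colnames(resids[[cv]])[j],
                             residual = unname(r[j]),
                             stringsAsFactors = FALSE)
        }
      }
      if (!is.null(best)) rows[[lev]] <- best
    }
  }
  attractors <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
                else data.frame(anchor_level = character(0), covariate = character(0),
                                level = character(0), residual = numeric(0))
  list(tests = tests, attractors = attractors)
}
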