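# Alpha diversity, Bray-Curtis distances, PCoA and single-factor PERMANOVA.

#' Shannon entropy (nats)
#'
#' H = -sum p_i ln p_i over taxa with nonzero counts.
#'
#' @param counts non-negative count vector with positive total
#' @return entropy in nats
#' @export
shannon_entropy <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  tot <- sum(counts)
  if (tot <= 0) stop("zero total count")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Expected rarefied richness
#'
#' Hypergeometric expectation of the number of taxa observed in a random
#' subsample of size n without replacement:
#' E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n)).
#'
#' @param counts non-negative count vector
#' @param depth subsample size n, must not exceed the total count
#' @return expected richness
#' @export
rarefied_richness <- function(counts, depth) {
  if (any(counts < 0)) stop("negative counts")
  N <- sum(counts)
  if (depth > N) stop("rarefaction depth exceeds total count")
  counts <- counts[counts > 0]
  # log-scale binomial ratios for numerical stability at large N
  lr <- lchoose(N - counts, depth) - lchoose(N, depth)
  sum(1 - exp(lr))
}

#' Bray-Curtis distance matrix
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i), optionally after converting
#' each sample to relative abundances.
#'
#' @param table an [abundance_table()] or numeric samples x taxa matrix
#' @param relative convert rows to relative abundances first? (default TRUE)
#' @return square symmetric matrix with zero diagonal, entries in [0, 1],
#'   dimnames = sample ids
#' @export
bray_curtis_matrix <- function(table, relative = TRUE) {
  m <- if (inherits(table, "abundance_table")) as_matrix(table) else as.matrix(table)
  if (nrow(m) < 2) stop("need at least 2 samples")
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("sample(s) with zero total: ",
                          paste(rownames(m)[tot <= 0], collapse = ", "))
  if (relative) m <- m / tot
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in (i + 1):n) {
      d <- sum(abs(xi - m[j, ])) / sum(xi + m[j, ])
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Principal Coordinate Analysis (classical MDS)
#'
#' Double-centres the squared distance matrix and eigendecomposes the Gram
#' matrix. Coordinates are returned for axes with positive eigenvalues;
#' negative eigenvalues (non-Euclidean distances) are reported, not corrected.
#'
#' @param dist square symmetric distance matrix
#' @return list with `coordinates` (samples x axes, ordered by eigenvalue)
#'   and `eigenvalues` (all, including negatives)
#' @export
pcoa <- function(dist) {
  D <- as.matrix(dist)
  stopifnot(nrow(D) == ncol(D))
  n <- nrow(D)
  A <- -0.5 * D^2
  B <- A - matrix(rowMeans(A), n, n) - matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > max(e$values) * 1e-10 & e$values > 0)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), length(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  list(coordinates = coords, eigenvalues = e$values)
}

ss_within <- function(d2, groups) {
  out <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    out <- out + sum(d2[idx, idx]) / (2 * length(idx))
  }
  out
}

unique_label_permutations <- function(labels) {
  # all distinct orderings of the multiset of labels (recursive enumeration)
  res <- list()
  rec <- function(prefix, remaining) {
    if (!length(remaining)) {
      res[[length(res) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in unique(remaining)) {
      rec(c(prefix, lab), remaining[-match(lab, remaining)])
    }
  }
  rec(character(0), labels)
  res
}

#' Single-factor PERMANOVA
#'
#' Pseudo-F from the distance matrix: SS_total = sum of squared distances / n,
#' SS_within from within-group pair sums, SS_between = SS_total - SS_within,
#' F = (SS_between/(a-1)) / (SS_within/(n-a)), R^2 = SS_between/SS_total.
#' The p-value permutes group labels; with `n_permutations = "exhaustive"` all
#' distinct label assignments are enumerated and p is the exact proportion
#' with F >= F_observed (the identity assignment included). Monte-Carlo mode
#' applies the +1 correction: p = (1 + #{F_perm >= F_obs}) / (1 + B).
#'
#' @param dist square symmetric distance matrix
#' @param grouping factor or character vector of group labels, aligned with
#'   the rows of `dist`
#' @param n_permutations number of random permutations (default 999) or
#'   `"exhaustive"`
#' @param seed RNG seed for the permutations (default NULL: leave RNG state)
#' @return list with `f`, `r_squared`, `p_value`, `n_permutations`, `df`
#' @export
permanova <- function(dist, grouping, n_permutations = 999, seed = NULL) {
  D <- as.matrix(dist)
  groups <- factor(as.character(grouping))
  n <- nrow(D)
  stopifnot(length(groups) == n)
  a <- nlevels(groups)
  if (a < 2) stop("PERMANOVA needs at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  d2 <- D^2
  sst <- sum(d2) / (2 * n)
  f_stat <- function(g) {
    ssw <- ss_within(d2, g)
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(groups)
  ssw_obs <- ss_within(d2, groups)
  r2 <- (sst - ssw_obs) / sst

  if (identical(n_permutations, "exhaustive")) {
    perms <- unique_label_permutations(as.character(groups))
    f_perm <- vapply(perms, function(g) f_stat(factor(g, levels = levels(groups))),
                     numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    B <- length(perms)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    B <- n_permutations
    f_perm <- replicate(B, f_stat(groups[sample.int(n)]))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + B)
  }
  list(f = f_obs, r_squared = r2, p_value = p, n_permutations = B,
       df = c(between = a - 1, within = n - a))
}

#' Per-sample alpha diversity table
#'
#' @param table an [abundance_table()]
#' @param rarefaction_depth subsample size for rarefied richness; default the
#'   minimum sample depth
#' @return data.frame: sample_id, depth, shannon, rarefied_richness
#' @export
alpha_diversity <- function(table, rarefaction_depth = NULL) {
  m <- as_matrix(table)
  depths <- rowSums(m)
  if (is.null(rarefaction_depth)) rarefaction_depth <- min(depths)
  data.frame(
    sample_id = sample_ids(table),
    depth = unname(depths),
    shannon = apply(m, 1, shannon_entropy),
    rarefied_richness = apply(m, 1, rarefied_richness, depth = rarefaction_depth),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
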