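# Shared fixtures and independent oracles.

toy_table <- function() {
  m <- matrix(c(10, 0, 5,
                2, 8, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
  abundance_table(m)
}

random_table <- function(n_samples, n_taxa, lambda = 5, zero_frac = 0.25) {
  m <- matrix(stats::rpois(n_samples * n_taxa, lambda), n_samples, n_taxa)
  m[sample(length(m), round(zero_frac * length(m)))] <- 0
  # guard against all-zero samples
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  abundance_table(m, sprintf("s%d", seq_len(n_samples)),
                  sprintf("t%d", seq_len(n_taxa)))
}

toy_taxonomy <- function() {
  df <- data.frame(
    Kingdom = c("Bacteria", "Bacteria", "Bacteria", ""),
    Phylum = c("Firmicutes", "Proteobacteria", "", ""),
    Class = c("Bacilli", "Alphaproteobacteria", "", ""),
    Order = c("Lactobacillales", "Rickettsiales", "", ""),
    Family = c("Lactobacillaceae", "Mitochondria", "", ""),
    Genus = c("Lactobacillus", "", "", ""),
    Species = c("", "", "", ""),
    stringsAsFactors = FALSE
  )
  rownames(df) <- c("t_firm", "t_mito", "t_kingdom_only", "t_unassigned")
  df
}

# Brute-force per-pair Bray-Curtis contribution oracle: non-core entries
# zeroed in the numerator, denominator from the full (relative) table.
bc_curve_oracle <- function(table, ranking, relative = TRUE) {
  m <- unclass(table)[, ranking, drop = FALSE]
  if (relative) m <- m / rowSums(m)
  n <- nrow(m)
  vapply(seq_along(ranking), function(k) {
    core <- seq_len(k)
    vals <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      x <- m[i, ]; y <- m[j, ]
      denom <- sum(x + y)
      bc_all <- sum(abs(x - y)) / denom
      if (bc_all > 0) {
        bc_core <- sum(abs(x[core] - y[core])) / denom
        vals <- c(vals, bc_core / bc_all)
      }
    }
    mean(vals)
  }, numeric(1))
}

# Brute-force PERMANOVA sums of squares from the distance matrix.
permanova_ss_oracle <- function(D, groups) {
  groups <- factor(groups)
  n <- nrow(D)
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + D[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    acc <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
        acc <- acc + D[idx[a], idx[b]]^2
    }
    ssw <- ssw + acc / length(idx)
  }
  list(sst = sst, ssw = ssw, ssb = sst - ssw)
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail
# P(X >= k_c) with fixed margins, via explicit binomial-coefficient sums.
hyper_tail_oracle <- function(k_c, n_c, k_s, n_s) {
  K <- k_c + k_s
  total <- choose(n_c + n_s, K)
  ks <- k_c:min(K, n_c)
  sum(choose(n_c, ks) * choose(n_s, K - ks)) / total
}
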