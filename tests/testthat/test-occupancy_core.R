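md_groups <- function(tab, labels) {
  data.frame(site = labels, is_negative_control = FALSE,
             row.names = sample_ids(tab), stringsAsFactors = FALSE)
}

test_that("group occupancy counts detections per group", {
  m <- matrix(0, 8, 3, dimnames = list(sprintf("s%d", 1:8),
                                       c("ubiq", "half_a", "absent")))
  m[, 1] <- 5
  m[1:2, 2] <- 3                      # 2 of 4 samples in group A only
  m[, 3] <- 0
  m[rowSums(m) == 0, 1] <- 1
  tab <- abundance_table(m)
  md <- md_groups(tab, rep(c("A", "B"), each = 4))
  occ <- group_occupancy(tab, md, "site")
  expect_equal(occ["ubiq", ], c(A = 1, B = 1))
  expect_equal(occ["half_a", ], c(A = 0.5, B = 0))
  expect_equal(occ["absent", ], c(A = 0, B = 0))
  # pooled model: one group over all samples
  pooled <- group_occupancy(tab, grouping = "none")
  expect_equal(dim(pooled), c(3L, 1L))
  expect_equal(pooled["half_a", 1], 0.25)
})

test_that("ranking index follows the occupancy + replicate-consistency formula", {
  m <- matrix(0, 8, 3, dimnames = list(sprintf("s%d", 1:8),
                                       c("full", "half", "absent")))
  m[, "full"] <- 10
  m[c(1, 2, 5, 6), "half"] <- 4       # occupancy 0.5 in each group, never complete
  tab <- abundance_table(m)
  md <- md_groups(tab, rep(c("A", "B"), each = 4))
  rk <- rank_taxa(tab, md, "site")
  idx <- setNames(rk$index, rk$taxon_id)
  expect_equal(idx[["full"]], 1)               # (2 + 2) / 4
  expect_equal(idx[["half"]], 0.25)            # (1 + 0) / 4
  expect_equal(idx[["absent"]], 0)
  expect_equal(rk$taxon_id, c("full", "half", "absent"))
  expect_equal(rk$rank, 1:3)
})

test_that("ranking is invariant to sample and taxon order; single group sorts by occupancy", {
  set.seed(1)
  tab <- random_table(10, 12)
  rk <- rank_taxa(tab)
  perm_s <- sample(nrow(tab))
  perm_t <- sample(ncol(tab))
  tab2 <- abundance_table(unclass(tab)[perm_s, perm_t])
  rk2 <- rank_taxa(tab2)
  expect_equal(rk2$taxon_id, rk$taxon_id)
  expect_equal(rk2$index, rk$index)
  # single group: index ordering equals occupancy ordering
  expect_equal(rk$index, (rk$overall_occupancy + (rk$overall_occupancy == 1)) / 2)
  expect_true(all(diff(rk$overall_occupancy) <= 0))
})

test_that("contribution curve matches the brute-force pairwise oracle", {
  set.seed(2)
  for (i in 1:25) {
    tab <- random_table(5, 8)
    rk <- rank_taxa(tab)$taxon_id
    expect_equal(bc_contribution_curve(tab, rk),
                 bc_curve_oracle(tab, rk), tolerance = 1e-12)
  }
  # counts mode agrees with its oracle too
  tab <- random_table(4, 6)
  rk <- rank_taxa(tab)$taxon_id
  expect_equal(bc_contribution_curve(tab, rk, relative = FALSE),
               bc_curve_oracle(tab, rk, relative = FALSE), tolerance = 1e-12)
})

test_that("contribution curve is monotone with unit endpoint and guards its inputs", {
  set.seed(3)
  tab <- random_table(6, 10)
  rk <- rank_taxa(tab)$taxon_id
  curve <- bc_contribution_curve(tab, rk)
  expect_true(all(diff(curve) >= -1e-9))
  expect_equal(curve[length(curve)], 1)
  expect_error(bc_contribution_curve(abundance_table(unclass(tab)[1, , drop = FALSE]), rk),
               "2 samples")
  ident <- abundance_table(matrix(3, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))))
  expect_error(bc_contribution_curve(ident, c("x", "y")), "identical")
})

test_that("last-2% rule stops at the first sub-threshold gain", {
  expect_equal(select_core_last2pct(c(0.50, 0.60, 0.63, 0.635))$k, 3)
  expect_equal(select_core_last2pct(c(0.4, 0.4, 0.4))$k, 1)          # flat after rank 1
  growing <- cumprod(rep(1.03, 10))
  expect_equal(select_core_last2pct(growing)$k, 10)                  # grows >= 2% throughout
  # leading zeros are included up to the first positive contribution
  expect_equal(select_core_last2pct(c(0, 0, 0.5, 0.505))$k, 3)
  expect_error(select_core_last2pct(numeric(0)), "empty")
})

test_that("elbow rule maximises the difference of segment rates of change", {
  expect_equal(select_core_elbow(c(0.1, 0.2, 0.3, 0.9, 0.91, 0.92))$k, 4)
  expect_equal(select_core_elbow(c(0, 1, 1, 1))$k, 2)                # single step at rank 2
  linear <- (1:6) * 0.25
  res <- select_core_elbow(linear)
  expect_equal(res$k, 2)                                             # all-zero ties -> first interior
  expect_equal(max(abs(res$fo_diff), na.rm = TRUE), 0)
  expect_error(select_core_elbow(c(0.1, 0.2)), "length >= 3")
})

test_that("phylum composition partitions the core with an Unknown bucket", {
  tax <- toy_taxonomy()
  comp <- core_phylum_composition(c("t_firm", "t_mito", "t_kingdom_only"), tax)
  expect_equal(sum(comp), 3)
  expect_equal(comp[["Firmicutes"]], 1)
  expect_equal(comp[["Unknown"]], 1)
  expect_length(core_phylum_composition(character(0), tax), 0)
})

test_that("site-specific occupancy never raises the core's minimum occupancy", {
  ds <- generate_synthetic_dataset(synthetic_config(
    n_taxa = 150, samples_per_cell = 3, n_contaminants = 0, n_controls = 0,
    seed = 21))
  pooled <- select_core(ds$table, ds$metadata, "none")
  site <- select_core(ds$table, ds$metadata, "province")
  expect_lte(site$min_occupancy_last2pct, pooled$min_occupancy_last2pct)
})
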