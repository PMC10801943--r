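test_that("abundance tables round-trip through TSV in either orientation", {
  tab <- toy_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, path)
  back <- read_abundance_table(path, "tsv")
  expect_identical(unclass(back), unclass(tab))

  # taxa-as-rows on disk reads back to the same canonical table
  tpath <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(taxon_id = taxon_ids(tab), t(unclass(tab)),
                   check.names = FALSE)
  write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  back_t <- read_abundance_table(tpath, "tsv", orientation = "taxa_as_rows")
  expect_identical(unclass(back_t), unclass(tab))
})

test_that("malformed tables are rejected with informative errors", {
  expect_error(abundance_table(matrix(1:4, 2), c("a", "a"), c("x", "y")),
               "duplicate sample")
  expect_error(abundance_table(matrix(c(1, -1, 2, 3), 2)), "negative")
  expect_error(abundance_table(matrix(c(1, 1.5, 2, 3), 2)), "non-integral")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tt1\tt2", "s1\t3\toops", "s2\t1\t2"), path)
  expect_error(read_abundance_table(path), "non-numeric cell.*t2")
})

test_that("low-yield filter keeps samples at exactly the threshold", {
  m <- matrix(c(1500, 2500, 2000), ncol = 1,
              dimnames = list(c("a", "b", "c"), "t1"))
  res <- filter_low_yield_samples(abundance_table(m), 2000)
  expect_setequal(sample_ids(res$table), c("b", "c"))
  expect_equal(res$removed$sample_id, "a")
  expect_equal(res$removed$depth, 1500)
  # retained + removed depths account for the input total
  expect_equal(sum(res$table) + sum(res$removed$depth), sum(m))

  expect_identical(filter_low_yield_samples(abundance_table(m), 0)$table,
                   abundance_table(m))
  low <- abundance_table(matrix(rep(1999, 3), ncol = 1,
                                dimnames = list(letters[1:3], "t1")))
  expect_error(filter_low_yield_samples(low, 2000), "all samples")
})

test_that("lineage filter removes organelles and fully unassigned taxa", {
  m <- matrix(5, 2, 4, dimnames = list(c("s1", "s2"),
                                       rownames(toy_taxonomy())))
  tab <- abundance_table(m)
  res <- filter_taxa_by_lineage(tab, toy_taxonomy(),
                                exclude_terms = c(Family = "Mitochondria"),
                                drop_fully_unassigned = TRUE)
  expect_setequal(res$removed, c("t_mito", "t_unassigned"))
  expect_setequal(taxon_ids(res$table), c("t_firm", "t_kingdom_only"))
  # counts of retained taxa untouched
  expect_true(all(unclass(res$table) == 5))
  # idempotent
  twice <- filter_taxa_by_lineage(res$table, toy_taxonomy(),
                                  c(Family = "Mitochondria"), TRUE)
  expect_identical(unclass(twice$table), unclass(res$table))
  expect_error(filter_taxa_by_lineage(tab, toy_taxonomy(),
                                      c(Tribe = "x")), "unknown rank")
})

test_that("taxonomy reader parses lineage strings and strips SILVA prefixes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tlineage",
               "t1\td__Bacteria;p__Firmicutes;c__Bacilli",
               "t2\tD_0__Bacteria;D_1__Proteobacteria"), path)
  tax <- read_taxonomy(path)
  expect_equal(tax["t1", "Phylum"], "Firmicutes")
  expect_equal(tax["t2", "Phylum"], "Proteobacteria")
  expect_equal(tax["t1", "Species"], "")   # missing ranks become empty, kept
})

test_that("prevalence contaminant score matches the enumeration oracle", {
  # 94 samples: 4 controls, 90 true
  ids <- c(sprintf("nc%d", 1:4), sprintf("s%02d", 1:90))
  md <- data.frame(is_negative_control = c(rep(TRUE, 4), rep(FALSE, 90)),
                   row.names = ids)
  m <- matrix(0L, 94, 3, dimnames = list(ids, c("everywhere_nc", "clean", "mixed")))
  m[1:4, 1] <- 100                       # all controls, no true samples
  m[5:94, 2] <- 10                       # never in controls
  m[c(1:3, 5:9), 3] <- 7                 # 3 of 4 controls, 5 of 90 samples
  res <- identify_contaminants_prevalence(abundance_table(m), md, threshold = 0.1)
  res <- res[match(colnames(m), res$taxon_id), ]
  expect_true(res$flagged[1])
  expect_false(res$flagged[2])
  expect_equal(res$score[2], 1)          # never flagged at any threshold < 1
  expect_equal(res$score[3], hyper_tail_oracle(3, 4, 5, 90), tolerance = 1e-12)

  no_nc <- data.frame(is_negative_control = rep(FALSE, 94), row.names = ids)
  expect_error(identify_contaminants_prevalence(abundance_table(m), no_nc),
               "skip")
})

test_that("preprocess_table applies the fixed filter order and is idempotent", {
  set.seed(42)
  ds <- generate_synthetic_dataset(synthetic_config(
    n_taxa = 60, samples_per_cell = 2, n_selected = 0,
    n_dispersal_limited = 0, n_contaminants = 5, seed = 9))
  pre <- preprocess_table(ds$table, ds$metadata, min_reads = 2000)
  expect_false(any(ds$metadata[sample_ids(pre$table), "is_negative_control"]))
  truth_cont <- ds$truth$taxon_id[ds$truth$class == "contaminant"]
  expect_true(all(truth_cont %in% pre$report$contaminants_removed))
  again <- preprocess_table(pre$table, ds$metadata, min_reads = 2000)
  expect_identical(unclass(again$table), unclass(pre$table))
})
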