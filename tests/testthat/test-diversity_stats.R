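test_that("Shannon entropy (nats) matches hand-computed values", {
  expect_equal(shannon_entropy(c(10, 10, 10, 10)), log(4))
  expect_equal(shannon_entropy(c(100, 0, 0)), 0)
  p <- (1:3) / 6
  expect_equal(shannon_entropy(c(1, 2, 3)), -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(1, 2, 3)), 1.0114, tolerance = 1e-4)
  expect_error(shannon_entropy(c(0, 0)), "zero total")
})

test_that("rarefied richness follows the hypergeometric expectation", {
  expect_equal(rarefied_richness(c(5, 5), 2), 2 * (1 - 10 / 45), tolerance = 1e-12)
  v <- c(7, 3, 1, 0, 12)
  expect_equal(rarefied_richness(v, sum(v)), sum(v > 0))    # n = N
  expect_equal(rarefied_richness(c(3, 0, 0), 3), 1)
  expect_error(rarefied_richness(c(2, 2), 5), "exceeds")
  # agrees with vegan's rarefy on a non-trivial vector
  expect_equal(rarefied_richness(v, 5),
               as.numeric(vegan::rarefy(v, 5)), tolerance = 1e-9)
})

test_that("rarefied richness matches exhaustive random subsampling", {
  v <- c(6, 3, 1)
  n <- 4
  set.seed(9)
  pool <- rep(seq_along(v), v)
  draws <- replicate(20000, length(unique(sample(pool, n))))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(rarefied_richness(v, n) - mean(draws)), 3 * se)
})

test_that("Bray-Curtis distances match definitions and the vegan oracle", {
  m <- rbind(a = c(6, 2), b = c(2, 2))
  D <- bray_curtis_matrix(m, relative = FALSE)
  expect_equal(D["a", "b"], 4 / 12, tolerance = 1e-12)
  same <- rbind(x = c(3, 1), y = c(3, 1))
  expect_equal(bray_curtis_matrix(same, relative = FALSE)["x", "y"], 0)
  disjoint <- rbind(x = c(5, 0), y = c(0, 7))
  expect_equal(bray_curtis_matrix(disjoint, relative = FALSE)["x", "y"], 1)

  set.seed(10)
  tab <- random_table(7, 9)
  D2 <- bray_curtis_matrix(tab, relative = FALSE)
  expect_equal(D2[lower.tri(D2)],
               as.matrix(vegan::vegdist(unclass(tab), "bray"))[lower.tri(D2)],
               tolerance = 1e-12)
  # matrix invariants
  expect_equal(D2, t(D2))
  expect_true(all(diag(D2) == 0))
  expect_true(all(D2 >= 0 & D2 <= 1))
  expect_error(bray_curtis_matrix(rbind(c(0, 0), c(1, 2))), "zero total")
})

test_that("PCoA reproduces geometry and agrees with classical scaling", {
  # three mutually equidistant samples: two equal positive eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  eig <- pcoa(D3)$eigenvalues
  pos <- eig[eig > 1e-10]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  # points on a line: one dominant axis recovering the gaps
  x <- c(0, 1, 3, 7)
  D <- as.matrix(dist(x))
  res <- pcoa(D)
  expect_equal(sum(res$eigenvalues > 1e-8), 1)
  ax <- res$coordinates[, 1]
  expect_equal(as.matrix(dist(ax)), D, ignore_attr = TRUE, tolerance = 1e-9)

  # duplicate sample collapses to a zero-distance pair; matches cmdscale
  set.seed(11)
  tab <- random_table(5, 6)
  m <- rbind(unclass(tab), dup = unclass(tab)[1, ])
  Dd <- bray_curtis_matrix(m, relative = FALSE)
  coords <- pcoa(Dd)$coordinates
  expect_equal(coords[1, ], coords[6, ], tolerance = 1e-9)
  cmd <- cmdscale(Dd, k = 2)
  expect_equal(abs(coords[, 1:2]), abs(cmd), ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("PERMANOVA matches the brute-force decomposition and vegan", {
  set.seed(12)
  tab <- random_table(12, 8)
  D <- bray_curtis_matrix(tab)
  g <- rep(c("u", "v", "w"), each = 4)
  res <- permanova(D, g, n_permutations = 99, seed = 1)
  ss <- permanova_ss_oracle(D, g)
  expect_equal(res$r_squared, ss$ssb / ss$sst, tolerance = 1e-12)
  expect_equal(res$f, (ss$ssb / 2) / (ss$ssw / 9), tolerance = 1e-12)
  van <- vegan::adonis2(as.dist(D) ~ g, permutations = 99)
  expect_equal(res$f, van$F[1], tolerance = 1e-9)
  expect_equal(res$r_squared, van$R2[1], tolerance = 1e-9)
  # mutually equidistant samples: R2 from the oracle decomposition
  De <- matrix(1, 6, 6) - diag(6)
  ge <- rep(c("a", "b"), each = 3)
  sse <- permanova_ss_oracle(De, ge)
  expect_equal(permanova(De, ge, 19, seed = 2)$r_squared, sse$ssb / sse$sst)
  expect_error(permanova(D, rep("one", 12)), "2 groups")
})

test_that("exhaustive permutations give the exact p for separated 3+3 clusters", {
  m <- rbind(matrix(c(100, 1), 3, 2, byrow = TRUE) + 0:2,
             matrix(c(1, 100), 3, 2, byrow = TRUE) + 0:2)
  D <- bray_curtis_matrix(m)
  res <- permanova(D, rep(c("a", "b"), each = 3), "exhaustive")
  expect_equal(res$n_permutations, 20)   # 6!/(3!3!)
  expect_equal(res$p_value, 0.1)
})

test_that("Monte-Carlo p agrees with the exhaustive p within sampling error", {
  set.seed(13)
  tab <- random_table(7, 6)
  D <- bray_curtis_matrix(tab)
  g <- c("a", "a", "a", "b", "b", "b", "b")
  exact <- permanova(D, g, "exhaustive")$p_value
  mc <- permanova(D, g, n_permutations = 4000, seed = 3)$p_value
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(mc - exact), 4 * se + 1e-3)
})
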