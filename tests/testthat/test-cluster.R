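test_that("Spearman distances follow the rank-then-Pearson definition", {
  m <- cbind(s1 = c(1, 2, 3, 4, 5), s2 = c(2, 4, 6, 8, 100),
             s3 = c(5, 4, 3, 2, 1))
  rownames(m) <- paste0("f", 1:5)
  d <- spearman_distance_matrix(expr_matrix(m, "normalized_log2"))
  expect_equal(d["s1", "s2"], 0)          # rank concordant
  expect_equal(d["s1", "s3"], 2)          # rank discordant
  expect_equal(diag(d), setNames(rep(0, 3), colnames(m)))
  expect_true(isSymmetric(d))

  em <- rand_expr(12, 5, "normalized_log2", seed = 77,
                  gen = function(n) rnorm(n))
  d2 <- spearman_distance_matrix(em)
  v <- unclass(em)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d2[i, j], 1 - cor(rank(v[, i]), rank(v[, j])), tolerance = 1e-12)
  }
  expect_true(all(d2 >= 0 & d2 <= 2))
})

test_that("constant vectors and sparse overlaps are errors", {
  m <- cbind(s1 = c(1, 1, 1, 1), s2 = c(1, 2, 3, 4))
  rownames(m) <- paste0("f", 1:4)
  expect_error(spearman_distance_matrix(expr_matrix(m, "normalized_log2")),
               "constant values.*s1")
  m2 <- cbind(s1 = c(1, 2, NA, NA), s2 = c(1, NA, 2, 3))
  rownames(m2) <- paste0("f", 1:4)
  expect_error(spearman_distance_matrix(expr_matrix(m2, "normalized_log2")),
               "complete observations")
})

test_that("Ward clustering recovers planted separation and matches hclust", {
  set.seed(13)
  x <- cbind(matrix(rnorm(5 * 6, 0, 0.3), 5, 6),
             matrix(rnorm(5 * 6, 5, 0.3), 5, 6))
  colnames(x) <- paste0("s", 1:12)
  rownames(x) <- paste0("f", 1:5)
  d <- as.matrix(dist(t(x)))
  dend <- ward_cluster(d, k = 2)
  expect_equal(unname(dend$clusters), rep(c(1L, 2L), each = 6))
  # Lance-Williams Ward on raw distances is hclust's ward.D
  hc <- hclust(as.dist(d), method = "ward.D")
  expect_equal(dend$hclust$height, hc$height, tolerance = 1e-10)
  expect_equal(cutree(dend$hclust, 2), cutree(hc, 2))
  # heights are monotone non-decreasing
  expect_true(all(diff(dend$hclust$height) >= -1e-12))
})

test_that("two leaves give a single trivial merge", {
  d <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  dend <- ward_cluster(d, k = 2)
  expect_equal(nrow(dend$hclust$merge), 1L)
  expect_equal(dend$hclust$height, 3)
  expect_equal(unname(dend$clusters), c(1L, 2L))
  expect_error(ward_cluster(d, k = 3), "k must lie")
})

test_that("label permutation yields the same partition up to relabeling", {
  set.seed(9)
  x <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(NULL, paste0("s", 1:10)))
  d <- as.matrix(dist(t(x)))
  a <- ward_cluster(d, k = 3)$clusters
  perm <- sample(colnames(d))
  b <- ward_cluster(d[perm, perm], k = 3)$clusters[names(a)]
  tab <- table(a, b)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("newick export round-trips through ape", {
  d <- as.matrix(dist(matrix(rnorm(20), 5, 4,
                             dimnames = list(paste0("s", 1:5), NULL))))
  dend <- ward_cluster(d, k = 2)
  txt <- dendrogram_newick(dend)
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, paste0("s", 1:5))
})

test_that("separation check reports purity against metadata", {
  meta <- sample_table(data.frame(sample_id = paste0("s", 1:6),
                                  diagnosis = "RA",
                                  smoker = rep(c(TRUE, FALSE), each = 3),
                                  condition = "control"))
  x <- cbind(matrix(rnorm(4 * 3, 0, 0.2), 4, 3), matrix(rnorm(4 * 3, 6, 0.2), 4, 3))
  colnames(x) <- paste0("s", 1:6)
  dend <- ward_cluster(as.matrix(dist(t(x))), k = 2)
  sep <- cluster_separation_check(dend, meta)
  expect_identical(sep$purity, 1)
  expect_true(sep$pure)
})

test_that("smoker clusters emerge from planted differential miRs", {
  # scaled-down version of the recovery simulation (12 seeds, not 100):
  # normalized cohort, clustering on the 8 planted miRs only
  pure <- 0L
  for (seed in 1:12) {
    sim <- simulate_microarray(microarray_sim_config(), seed = 4000 + seed)
    norm <- normalize_microarray(sim$raw, sim$noise)
    sub <- norm$normalized[names(sim$truth$planted_effects), , drop = FALSE]
    dend <- ward_cluster(spearman_distance_matrix(sub, center_features = TRUE),
                         k = 2)
    sep <- cluster_separation_check(dend, sim$meta)
    pure <- pure + sep$pure
  }
  expect_gte(pure, 9L)   # >= 80% of seeds, with 1-seed slack at n = 12
})

test_that("random labels give purity near the majority baseline", {
  set.seed(66)
  purities <- replicate(30, {
    x <- matrix(rnorm(6 * 12), 6, 12, dimnames = list(NULL, paste0("s", 1:12)))
    meta <- sample_table(data.frame(sample_id = paste0("s", 1:12),
                                    diagnosis = "RA",
                                    smoker = sample(rep(c(TRUE, FALSE), 6)),
                                    condition = "control"))
    dend <- ward_cluster(as.matrix(dist(t(x))), k = 2)
    cluster_separation_check(dend, meta)$purity
  })
  expect_lt(mean(purities), 0.85)   # nowhere near systematically pure
  expect_gte(mean(purities), 0.5)
})
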