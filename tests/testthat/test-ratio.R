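rq_fixture <- function(m) {
  out <- expr_matrix(m, "rq")
  attr(out, "normalization_scope") <- "vs_cohort_median"
  out
}

default_panel <- analyte_panel()

small_panel <- analyte_panel(mrna_ids = c("g1", "g2", "g3"),
                             mir_ids = c("m1", "m2", "m3"))

test_that("ratio is the quotient of panel-side median RQs", {
  m <- matrix(1, 6, 3, dimnames = list(c("g1", "g2", "g3", "m1", "m2", "m3"),
                                       c("s1", "s2", "s3")))
  rr <- mrna_mir_ratio(rq_fixture(m), small_panel)
  expect_equal(rr$ratio, rep(1, 3))

  m2 <- m
  m2[c("g1", "g2", "g3"), "s1"] <- c(2, 3, 4)
  rr2 <- mrna_mir_ratio(rq_fixture(m2), small_panel)
  expect_equal(rr2$ratio[rr2$sample_id == "s1"], 3)
})

test_that("ratios match a per-sample brute-force recomputation", {
  em <- rand_expr(6, 7, "rq", seed = 23, gen = function(n) exp(rnorm(n)))
  rownames(em) <- c("g1", "g2", "g3", "m1", "m2", "m3")
  rq <- relative_quantity_to_median(em)
  rr <- mrna_mir_ratio(rq, small_panel)
  v <- unclass(rq)
  for (i in seq_len(nrow(rr))) {
    s <- rr$sample_id[i]
    expect_equal(rr$ratio[i],
                 median(v[c("g1", "g2", "g3"), s]) / median(v[c("m1", "m2", "m3"), s]))
  }
  expect_error(mrna_mir_ratio(em, small_panel), "cohort median")
})

test_that("classification uses strict cutoffs with exact 2/3 lower bound", {
  rr <- data.frame(sample_id = paste0("s", 1:5),
                   median_rq_mrna = 1, median_rq_mir = 1,
                   ratio = c(3, 1, 0.5, 1.5, 2 / 3), group = NA_character_)
  class(rr) <- c("ratio_results", "data.frame")
  cl <- classify_ratio(rr)
  got <- setNames(cl$group, cl$sample_id)
  expect_equal(got[["s1"]], "high")
  expect_equal(got[["s2"]], "intermediate")
  expect_equal(got[["s3"]], "low")
  expect_equal(got[["s4"]], "intermediate")   # boundary 1.5
  expect_equal(got[["s5"]], "intermediate")   # boundary 1/1.5 exactly
  expect_equal(cl$ratio, sort(cl$ratio, decreasing = TRUE))
  expect_equal(unname(attr(cl, "group_sizes")), c(1L, 3L, 1L))
})

test_that("scaling only the mRNA side multiplies every ratio by c", {
  em <- rand_expr(6, 5, "rq", seed = 3, gen = function(n) exp(rnorm(n)))
  rownames(em) <- c("g1", "g2", "g3", "m1", "m2", "m3")
  rq <- relative_quantity_to_median(em)
  base <- mrna_mir_ratio(rq, small_panel)
  v <- unclass(rq)
  v[c("g1", "g2", "g3"), ] <- v[c("g1", "g2", "g3"), ] * 2.5
  scaled <- mrna_mir_ratio(rq_fixture(v), small_panel)
  expect_equal(scaled$ratio, base$ratio * 2.5)
  # scaling both sides equally leaves ratios unchanged
  v2 <- unclass(rq) * 7
  both <- mrna_mir_ratio(rq_fixture(v2), small_panel)
  expect_equal(both$ratio, base$ratio)
})

test_that("classification is permutation-equivariant in samples", {
  em <- rand_expr(6, 8, "rq", seed = 10, gen = function(n) exp(rnorm(n)))
  rownames(em) <- c("g1", "g2", "g3", "m1", "m2", "m3")
  rq <- relative_quantity_to_median(em)
  a <- classify_ratio(mrna_mir_ratio(rq, small_panel))
  perm <- rev(colnames(rq))
  rq_p <- rq_fixture(unclass(rq)[, perm])
  b <- classify_ratio(mrna_mir_ratio(rq_p, small_panel))
  expect_equal(a[order(a$sample_id), c("sample_id", "ratio", "group")],
               b[order(b$sample_id), c("sample_id", "ratio", "group")],
               ignore_attr = TRUE)
})

test_that("the default simulation recovers the planted 8/11/6 structure", {
  sim <- simulate_qpcr_cohort(qpcr_sim_config(), seed = 101)
  pipe <- qpcr_ratio_pipeline(sim)
  expect_equal(unname(attr(pipe$control, "group_sizes")), c(8L, 11L, 6L))
  got <- setNames(pipe$control$group, pipe$control$sample_id)
  expect_equal(got[names(sim$truth$groups)], sim$truth$groups)
})

test_that("paired shift recovers uniform-sign exact p-values", {
  sim <- simulate_qpcr_cohort(qpcr_sim_config(nicotine_inversion_strength = 1),
                              seed = 31)
  pipe <- qpcr_ratio_pipeline(sim)
  shift <- nicotine_response_shift(pipe$control, pipe$nicotine, sim$meta)
  high <- shift[shift$group == "high", ]
  low <- shift[shift$group == "low", ]
  expect_equal(high$n_pairs, 8L)
  expect_equal(high$decreased, 8L)
  expect_identical(high$p, 2 / 2^8)          # 0.0078125
  expect_equal(low$increased, 6L)
  expect_identical(low$p, 2 / 2^6)           # 0.03125
  expect_equal(shift$decreased + shift$increased + shift$tied, shift$n_pairs)
})

test_that("all-zero differences give p = 1 and unpaired samples warn", {
  rr <- function(ids, ratios, groups) {
    d <- data.frame(sample_id = ids, median_rq_mrna = 1, median_rq_mir = 1,
                    ratio = ratios, group = groups)
    class(d) <- c("ratio_results", "data.frame")
    d
  }
  meta <- sample_table(data.frame(
    sample_id = c("a_c", "b_c", "a_n", "b_n", "orphan"),
    diagnosis = "RA", smoker = FALSE,
    condition = c("control", "control", "nicotine", "nicotine", "control"),
    pair_id = c("A", "B", "A", "B", "C")))
  ctrl <- rr(c("a_c", "b_c", "orphan"), c(2, 2, 2), c("high", "high", "high"))
  nic <- rr(c("a_n", "b_n"), c(2, 2), c("high", "high"))
  expect_warning(shift <- nicotine_response_shift(ctrl, nic, meta), "orphan")
  expect_equal(shift$tied, 2L)
  expect_identical(shift$p, 1)
})
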