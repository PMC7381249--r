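noise_for <- function(em, mean = 10, sd = 5) {
  noise_stats(data.frame(sample_id = colnames(em), noise_mean = mean,
                         noise_sd = sd, stringsAsFactors = FALSE))
}

test_that("detection applies the noise-mean + k SD rule and subtracts background", {
  m <- matrix(c(25, 19, 20.0001, NA), 4, 1,
              dimnames = list(paste0("f", 1:4), "s1"))
  det <- detection_call(expr_matrix(m, "raw_intensity"), noise_for(m, 10, 5))
  expect_equal(unname(unclass(det$corrected)[, 1]), c(15, NA, 10.0001, NA))
  expect_equal(unname(det$mask[, 1]), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(det$detected_count_per_sample), 2L)
  expect_error(detection_call(expr_matrix(m, "raw_intensity"),
                              noise_stats(data.frame(sample_id = "other",
                                                     noise_mean = 1, noise_sd = 1))),
               "no noise record")
})

test_that("detection matches a cell-wise re-evaluation on seeded data", {
  em <- rand_expr(40, 6, seed = 11, gen = function(n) runif(n, 0, 60))
  ns <- noise_stats(data.frame(sample_id = colnames(em),
                               noise_mean = runif(6, 5, 15),
                               noise_sd = runif(6, 1, 6)))
  det <- detection_call(em, ns, k_sd = 2)
  for (s in seq_len(ncol(em))) {
    thr <- ns$noise_mean[s] + 2 * ns$noise_sd[s]
    for (f in seq_len(nrow(em))) {
      v <- unclass(em)[f, s]
      if (v > thr) {
        expect_true(det$mask[f, s])
        expect_equal(unclass(det$corrected)[f, s], max(v - ns$noise_mean[s], 0))
      } else {
        expect_false(det$mask[f, s])
        expect_true(is.na(unclass(det$corrected)[f, s]))
      }
    }
  }
  expect_equal(det$detected_count_per_sample, colSums(det$mask))
})

test_that("detection is idempotent on its corrected output under zero noise", {
  em <- rand_expr(30, 4, seed = 3, gen = function(n) runif(n, 0, 80))
  det1 <- detection_call(em, noise_for(em, 8, 3))
  zero <- noise_for(em, 0, 0)
  det2 <- detection_call(det1$corrected, zero)
  expect_equal(unclass(det2$corrected), unclass(det1$corrected))
  expect_equal(det2$mask, det1$mask)
})

test_that("sample QC excludes low-detection arrays and reports them", {
  mask <- matrix(FALSE, 1000, 3, dimnames = list(NULL, c("a", "b", "c")))
  mask[1:500, 1] <- TRUE; mask[1:480, 2] <- TRUE; mask[1:12, 3] <- TRUE
  corr <- matrix(runif(3000, 1, 9), 1000, 3,
                 dimnames = list(paste0("f", 1:1000), c("a", "b", "c")))
  corr[!mask] <- NA
  det <- structure(list(mask = mask, corrected = expr_matrix(corr, "raw_intensity"),
                        detected_count_per_sample = colSums(mask)),
                   class = "detection_result")
  qc <- qc_filter_samples(det, min_detected = 100)
  expect_equal(qc$retained, c("a", "b"))
  expect_equal(qc$excluded$sample_id, "c")
  expect_equal(qc$excluded$detected_count, 12L)
  expect_equal(qc_filter_samples(det, 0)$retained, c("a", "b", "c"))
  expect_error(qc_filter_samples(det, 1000), "all samples excluded")
})

test_that("expression filter keeps means strictly above the threshold", {
  m <- rbind(f1 = c(90, 110), f2 = c(79, 79), f3 = c(80, 82))
  colnames(m) <- c("s1", "s2")
  em <- expr_matrix(m, "raw_intensity")
  kept <- filter_top_expressed(em, 80)
  expect_equal(rownames(kept), c("f1", "f3"))
  expect_equal(attr(kept, "kept_count"), 2L)
  expect_equal(rownames(filter_top_expressed(em, 0)), rownames(em))
  expect_equal(rownames(filter_top_expressed(em, top_n = 1)), "f1")
  expect_error(filter_top_expressed(em, 1e6), "no features retained")
})

test_that("log2 transform and inverse round-trip", {
  m <- rbind(f1 = c(0, 127), f2 = c(3, 15))
  colnames(m) <- c("s1", "s2")
  lg <- log2_transform(expr_matrix(m, "raw_intensity"), offset = 1)
  expect_equal(unclass(lg)["f1", ], c(s1 = 0, s2 = 7))
  em <- rand_expr(25, 4, seed = 9, gen = function(n) runif(n, 0, 1000))
  expect_lt(max(abs(unclass(log2_inverse(log2_transform(em))) - unclass(em))), 1e-12)
  neg <- expr_matrix(matrix(c(0, 1), 1, 2, dimnames = list("f1", c("a", "b"))),
                     "raw_intensity")
  expect_error(log2_transform(neg, offset = 0), "> 0")
})

test_that("cyclic loess leaves identical arrays unchanged and removes offsets", {
  set.seed(21)
  base <- sort(rnorm(60, 8, 2))
  m <- cbind(s1 = base, s2 = base)
  rownames(m) <- sprintf("f%02d", 1:60)
  em <- expr_matrix(m, "log2")
  out <- cyclic_loess_normalize(em)
  expect_lt(max(abs(unclass(out) - unclass(em))), 1e-8)

  m2 <- cbind(s1 = base, s2 = base + 0.8)
  rownames(m2) <- rownames(m)
  out2 <- cyclic_loess_normalize(expr_matrix(m2, "log2"))
  expect_lt(abs(median(unclass(out2)[, 1] - unclass(out2)[, 2])), 1e-3)
})

test_that("cyclic loess per-pair median |M| does not increase across sweeps", {
  set.seed(5)
  m <- matrix(rnorm(4 * 80, 8, 1.5), 80, 4,
              dimnames = list(sprintf("f%02d", 1:80), paste0("s", 1:4)))
  m[, 2] <- m[, 2] + 0.6; m[, 4] <- m[, 4] - 0.4
  med_abs_m <- function(x) {
    pairs <- utils::combn(ncol(x), 2)
    max(apply(pairs, 2, function(p) abs(median(x[, p[1]] - x[, p[2]]))))
  }
  em <- expr_matrix(m, "log2")
  initial <- med_abs_m(m)
  worst <- initial
  for (it in 1:3) {
    out <- cyclic_loess_normalize(em, iterations = it)
    w <- med_abs_m(unclass(out))
    # sweeps are sequential half-adjustments, so the decrease is monotone
    # only up to a small ripple between consecutive sweeps
    expect_lte(w, worst + 0.05 * initial)
    worst <- w
  }
  expect_lt(worst, 0.3 * initial)
})

test_that("per-pair adjustments cancel: column sums shift but totals balance", {
  em <- rand_expr(50, 5, "log2", seed = 14, gen = function(n) rnorm(n, 8, 1))
  out <- cyclic_loess_normalize(em)
  # with no missing data every adjustment to i is matched by its negation on j
  expect_lt(abs(sum(unclass(out)) - sum(unclass(em))), 1e-9)
})

test_that("missing values are adjusted but never invented", {
  em <- rand_expr(60, 3, "log2", seed = 8, gen = function(n) rnorm(n, 8, 1))
  v <- unclass(em); v[1:5, 1] <- NA; v[10, ] <- NA
  em2 <- expr_matrix(v, "log2")
  out <- cyclic_loess_normalize(em2)
  expect_identical(is.na(unclass(out)), is.na(v))
  expect_error(cyclic_loess_normalize(em2, min_points = 100), "complete features")
})
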