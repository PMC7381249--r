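two_group_design <- function(ids, n_ref) {
  design_spec(stats::setNames(rep(c("reference", "test"),
                                  c(n_ref, length(ids) - n_ref)), ids))
}

test_that("two-group fit returns the mean difference and pooled variance", {
  m <- rbind(f1 = c(5.0, 5.0, 5.8, 5.8, 5.8),
             f2 = c(1, 1, 1, 1, 1))
  colnames(m) <- paste0("s", 1:5)
  em <- expr_matrix(m, "normalized_log2")
  fits <- fit_feature_models(em, two_group_design(colnames(m), 2))
  expect_equal(fits$fits$logfc, c(0.8, 0))
  expect_equal(fits$fits$s2, c(0, 0))
  expect_equal(fits$fits$df_resid, c(3, 3))
})

test_that("fits match the closed-form oracle on seeded data", {
  em <- rand_expr(30, 9, "normalized_log2", seed = 4,
                  gen = function(n) rnorm(n, 7, 1))
  v <- unclass(em); v[2, 1] <- NA; v[5, 6] <- NA
  em <- expr_matrix(v, "normalized_log2")
  des <- two_group_design(colnames(em), 4)
  fits <- fit_feature_models(em, des)$fits
  for (i in seq_len(nrow(fits))) {
    f <- fits$feature_id[i]
    r <- v[f, 1:4]; t <- v[f, 5:9]
    r <- r[!is.na(r)]; t <- t[!is.na(t)]
    expect_equal(fits$logfc[i], mean(t) - mean(r))
    expect_equal(fits$s2[i],
                 (sum((r - mean(r))^2) + sum((t - mean(t))^2)) /
                   (length(r) + length(t) - 2))
    expect_equal(fits$stdev_unscaled[i], sqrt(1 / length(r) + 1 / length(t)))
  }
})

test_that("features without usable data are skipped with a reason", {
  m <- rbind(f1 = c(NA, NA, 3, 4), f2 = c(1, 2, 3, 4))
  colnames(m) <- paste0("s", 1:4)
  fits <- fit_feature_models(expr_matrix(m, "normalized_log2"),
                             two_group_design(colnames(m), 2))
  expect_equal(fits$skipped$feature_id, "f1")
  expect_match(fits$skipped$reason, "empty group")
  expect_equal(fits$fits$feature_id, "f2")
})

test_that("covariate fits agree with lm()", {
  set.seed(31)
  n <- 12
  ids <- paste0("s", 1:n)
  grp <- rep(c(0, 1), each = n / 2)
  cov <- cbind(age = rnorm(n, 50, 8))
  rownames(cov) <- ids
  m <- matrix(rnorm(8 * n, 6), 8, n, dimnames = list(paste0("f", 1:8), ids))
  des <- design_spec(stats::setNames(ifelse(grp == 1, "test", "reference"), ids),
                     covariates = cov)
  fits <- fit_feature_models(expr_matrix(m, "normalized_log2"), des)$fits
  for (i in 1:8) {
    lmf <- summary(lm(m[i, ] ~ grp + cov))
    expect_equal(fits$logfc[i], unname(coef(lmf)["grp", "Estimate"]))
    expect_equal(fits$s2[i], lmf$sigma^2)
    expect_equal(fits$logfc[i] / (sqrt(fits$s2[i]) * fits$stdev_unscaled[i]),
                 unname(coef(lmf)["grp", "t value"]))
  }
})

test_that("moderation limits: d0 = 0 is the ordinary t, d0 = Inf pools", {
  em <- rand_expr(40, 10, "normalized_log2", seed = 17,
                  gen = function(n) rnorm(n, 6, 0.5))
  fits <- fit_feature_models(em, two_group_design(colnames(em), 5))
  ord <- ebayes_moderate(fits, d0_override = 0)
  f <- fits$fits
  t_classic <- f$logfc / (sqrt(f$s2) * f$stdev_unscaled)
  expect_lt(max(abs(ord$t_mod - t_classic)), 1e-12)
  expect_lt(max(abs(ord$p - 2 * pt(-abs(t_classic), f$df_resid))), 1e-12)

  inf <- ebayes_moderate(fits, d0_override = Inf, s02_override = 0.3)
  expect_lt(max(abs(inf$t_mod - f$logfc / (sqrt(0.3) * f$stdev_unscaled))), 1e-12)
  expect_lt(max(abs(inf$p - 2 * pnorm(-abs(inf$t_mod)))), 1e-12)
})

test_that("moderated statistics match the limma oracle within 1e-6", {
  set.seed(99)
  n1 <- 6; n2 <- 7; p <- 200
  x <- matrix(rnorm(p * (n1 + n2), sd = sqrt(rchisq(p, 4) / 4) * 0.4), p, n1 + n2)
  x[1:10, (n1 + 1):(n1 + n2)] <- x[1:10, (n1 + 1):(n1 + n2)] + 0.8
  dimnames(x) <- list(sprintf("f%03d", 1:p), paste0("s", 1:(n1 + n2)))
  em <- expr_matrix(x, "normalized_log2")
  mine <- ebayes_moderate(fit_feature_models(em, two_group_design(colnames(x), n1)))
  oracle <- limma::eBayes(limma::lmFit(x, cbind(1, rep(0:1, c(n1, n2)))))
  expect_lt(abs(attr(mine, "d0") - oracle$df.prior), 1e-6)
  expect_lt(abs(attr(mine, "s02") - oracle$s2.prior), 1e-6)
  expect_lt(max(abs(mine$t_mod - oracle$t[, 2])), 1e-6)
  expect_lt(max(abs(mine$p - oracle$p.value[, 2])), 1e-6)
})

test_that("selection uses strict cutoffs and deterministic ordering", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    logfc = c(0.5, 0.51, -0.6, 2),
                    t_mod = 1, p = c(0.001, 0.002, 0.002, 0.2),
                    p_adj = c(0.004, 0.008, 0.008, 0.2),
                    df_total = 10, direction = "ns")
  class(res) <- c("moderated_result", "data.frame")
  sel <- select_differential(res)
  expect_equal(sel$up$feature_id, "b")        # 0.5 exactly is excluded
  expect_equal(sel$down$feature_id, "c")
  expect_equal(sel$results$feature_id, c("a", "b", "c", "d"))  # p then id
  none <- select_differential(res, lfc_cut = 10)
  expect_equal(nrow(none$up), 0L)
  expect_equal(nrow(none$down), 0L)
})

test_that("swapping group labels negates effects and preserves p", {
  em <- rand_expr(25, 8, "normalized_log2", seed = 55,
                  gen = function(n) rnorm(n, 5, 0.7))
  ids <- colnames(em)
  a <- ebayes_moderate(fit_feature_models(em, two_group_design(ids, 4)))
  swapped <- design_spec(stats::setNames(
    rep(c("test", "reference"), c(4, 4)), ids))
  b <- ebayes_moderate(fit_feature_models(em, swapped))
  expect_lt(max(abs(a$logfc + b$logfc)), 1e-12)
  expect_lt(max(abs(a$t_mod + b$t_mod)), 1e-12)
  expect_lt(max(abs(a$p - b$p)), 1e-12)
})
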