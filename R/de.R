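#' Two-group design specification
#'
#' Maps each analyzed sample to the reference or test group (non-smoker =
#' reference, smoker = test in the smoking contrast) with an optional numeric
#' covariate matrix.
#'
#' @param group named character vector (`"reference"`/`"test"`), names are
#'   sample ids; both groups must be non-empty.
#' @param covariates optional numeric matrix/data.frame, one row per sample
#'   (rownames = sample ids).
#' @return list of class `design_spec`.
#' @export
design_spec <- function(group, covariates = NULL) {
  if (is.null(names(group)) || anyDuplicated(names(group)))
    stop("`group` must be a named vector with unique sample ids", call. = FALSE)
  bad <- setdiff(unique(group), c("reference", "test"))
  if (length(bad)) stop("invalid group value(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!all(c("reference", "test") %in% group))
    stop("both groups must be non-empty", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(rownames(covariates)))
      stop("covariates need sample-id rownames", call. = FALSE)
    missing_cov <- setdiff(names(group), rownames(covariates))
    if (length(missing_cov))
      stop("covariates missing for: ", paste(missing_cov, collapse = ", "),
           call. = FALSE)
    covariates <- covariates[names(group), , drop = FALSE]
  }
  structure(list(group = group, covariates = covariates), class = "design_spec")
}

#' Build a design from sample metadata
#'
#' @param meta a [sample_table()].
#' @param contrast `"smoker"` (non-smoker reference) or `"diagnosis"`
#'   (HC reference).
#' @param samples restrict to these sample ids (default: all in `meta`).
#' @return a [design_spec()].
#' @export
design_from_metadata <- function(meta, contrast = c("smoker", "diagnosis"),
                                 samples = meta$sample_id) {
  contrast <- match.arg(contrast)
  m <- meta[match(samples, meta$sample_id), , drop = FALSE]
  grp <- if (contrast == "smoker") {
    ifelse(m$smoker, "test", "reference")
  } else {
    ifelse(m$diagnosis == "RA", "test", "reference")
  }
  design_spec(stats::setNames(grp, m$sample_id))
}

#' Per-feature linear-model fits
#'
#' Ordinary least squares per feature on non-missing samples; in the plain
#' two-group case the group coefficient is the test-minus-reference mean
#' difference (the log2 fold change on normalized data) and `s2` is the pooled
#' residual variance on `df_resid = n_used - rank` degrees of freedom.
#' Features with an empty group or no residual degrees of freedom are skipped
#' with a reason.
#'
#' @param mat `expr_matrix`, kind `normalized_log2`.
#' @param design a [design_spec()] covering the matrix's samples.
#' @return list of class `feature_fits`: data.frame `fits` (`feature_id`,
#'   `logfc`, `s2`, `df_resid`, `stdev_unscaled`, `n_used`) and data.frame
#'   `skipped` (`feature_id`, `reason`).
#' @export
fit_feature_models <- function(mat, design) {
  check_kind(mat, "normalized_log2", "fit_feature_models")
  stopifnot(inherits(design, "design_spec"))
  ids <- intersect(colnames(mat), names(design$group))
  if (!length(ids)) stop("no overlap between matrix samples and design", call. = FALSE)
  x <- unclass(mat)[, ids, drop = FALSE]
  grp <- design$group[ids]
  if (is.null(design$covariates)) {
    fits <- fit_two_group(x, grp == "test")
  } else {
    X <- cbind(intercept = 1, group = as.numeric(grp == "test"),
               design$covariates[ids, , drop = FALSE])
    fits <- fit_lm_rows(x, X)
  }
  ok <- !is.na(fits$logfc)
  skipped <- data.frame(feature_id = rownames(x)[!ok],
                        reason = fits$reason[!ok], stringsAsFactors = FALSE)
  out <- data.frame(feature_id = rownames(x)[ok], logfc = fits$logfc[ok],
                    s2 = fits$s2[ok], df_resid = fits$df[ok],
                    stdev_unscaled = fits$su[ok], n_used = fits$n[ok],
                    stringsAsFactors = FALSE)
  structure(list(fits = out, skipped = skipped), class = "feature_fits")
}

# vectorized two-group OLS with per-feature missingness
fit_two_group <- function(x, is_test) {
  xt <- x[, is_test, drop = FALSE]
  xr <- x[, !is_test, drop = FALSE]
  n1 <- rowSums(!is.na(xr)); n2 <- rowSums(!is.na(xt))
  m1 <- rowMeans(xr, na.rm = TRUE); m2 <- rowMeans(xt, na.rm = TRUE)
  ss <- rowSums((xr - m1)^2, na.rm = TRUE) + rowSums((xt - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  ok <- n1 >= 1 & n2 >= 1 & df >= 1
  reason <- rep(NA_character_, nrow(x))
  reason[n1 < 1 | n2 < 1] <- "empty group after missing-data removal"
  reason[n1 >= 1 & n2 >= 1 & df < 1] <- "no residual degrees of freedom"
  list(logfc = ifelse(ok, m2 - m1, NA_real_),
       s2 = ifelse(ok, ss / df, NA_real_),
       df = ifelse(ok, df, NA_integer_),
       su = ifelse(ok, sqrt(1 / n1 + 1 / n2), NA_real_),
       n = n1 + n2, reason = reason)
}

# row-wise OLS with covariates; group coefficient is column "group"
fit_lm_rows <- function(x, X) {
  p <- nrow(x)
  logfc <- s2 <- su <- rep(NA_real_, p)
  df <- n <- rep(NA_integer_, p)
  reason <- rep(NA_character_, p)
  for (f in seq_len(p)) {
    y <- x[f, ]
    use <- !is.na(y)
    Xf <- X[use, , drop = FALSE]
    n[f] <- sum(use)
    if (length(unique(Xf[, "group"])) < 2) { reason[f] <- "empty group after missing-data removal"; next }
    qrX <- qr(Xf)
    if (qrX$rank < ncol(Xf)) { reason[f] <- "rank-deficient design"; next }
    dff <- sum(use) - qrX$rank
    if (dff < 1) { reason[f] <- "no residual degrees of freedom"; next }
    fit <- stats::lm.fit(Xf, y[use])
    xtxi <- chol2inv(qr.R(qrX))
    k <- which(colnames(Xf) == "group")
    logfc[f] <- fit$coefficients[k]
    s2[f] <- sum(fit$residuals^2) / dff
    su[f] <- sqrt(xtxi[k, k])
    df[f] <- dff
  }
  list(logfc = logfc, s2 = s2, df = df, su = su, n = n, reason = reason)
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-feature residual variances toward a pooled prior fitted by
#' method of moments on the log variances (a scaled F / scaled inverse
#' chi-square hierarchy): with prior degrees of freedom d0 and prior variance
#' s0^2, the posterior variance is `(d0*s0^2 + df*s2) / (d0 + df)` and the
#' moderated t is the coefficient over its posterior standard error, referred
#' to a t distribution on `df + d0` degrees of freedom (normal when d0 is
#' infinite). `d0 = 0` recovers the ordinary t.
#'
#' @param fits a [fit_feature_models()] result.
#' @param d0_override force the prior degrees of freedom (0, `Inf`, or any
#'   positive number) instead of estimating them.
#' @param s02_override force the prior variance (used with `d0_override`).
#' @param var_floor variance floor applied to exact-zero `s2` before
#'   moderation, avoiding infinite statistics.
#' @return data.frame of class `moderated_result`: `feature_id`, `logfc`,
#'   `t_mod`, `p`, `p_adj` (Benjamini-Hochberg), `df_total`, `direction`
#'   (filled by [select_differential()], `"ns"` here); attributes `d0`, `s02`.
#' @export
ebayes_moderate <- function(fits, d0_override = NULL, s02_override = NULL,
                            var_floor = 1e-8) {
  stopifnot(inherits(fits, "feature_fits"))
  f <- fits$fits
  if (!nrow(f)) stop("no fitted features to moderate", call. = FALSE)
  s2 <- pmax(f$s2, var_floor)
  if (is.null(d0_override)) {
    if (all(f$s2 <= 0))
      stop("all residual variances are zero; supply d0_override", call. = FALSE)
    pr <- fit_f_dist(s2, f$df_resid)
    d0 <- pr$df2; s02 <- pr$s02
  } else {
    d0 <- d0_override
    s02 <- if (!is.null(s02_override)) s02_override else {
      if (is.infinite(d0)) exp(mean(log(s2))) else mean(s2)
    }
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s02, nrow(f))
    df_total <- rep(Inf, nrow(f))
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- f$df_resid
  } else {
    s2_post <- (d0 * s02 + f$df_resid * s2) / (d0 + f$df_resid)
    df_total <- pmin(f$df_resid + d0, sum(f$df_resid))
  }
  t_mod <- f$logfc / (sqrt(s2_post) * f$stdev_unscaled)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(feature_id = f$feature_id, logfc = f$logfc, t_mod = t_mod,
                    p = p, p_adj = stats::p.adjust(p, method = "BH"),
                    df_total = df_total, direction = "ns",
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  class(out) <- c("moderated_result", "data.frame")
  out
}

# Method-of-moments fit of a scaled F distribution to sample variances:
# log s2 ~ log s0^2 + log F(df, d0) up to digamma/trigamma corrections.
fit_f_dist <- function(s2, df) {
  s2 <- pmax(s2, 1e-300)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(z)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    df2 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(df2 / 2) - log(df2 / 2))
  } else {
    df2 <- Inf
    s02 <- exp(emean)
  }
  list(df2 = df2, s02 = s02)
}

# Solve trigamma(y) = x by Newton iteration on 1/trigamma (monotone convex).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Select differentially expressed features
#'
#' The published rule: increased means p below `p_cut` and logFC strictly
#' above `lfc_cut`; decreased means p below `p_cut` and logFC strictly below
#' `-lfc_cut`. Raw p is used by default (adjusted p is reported alongside).
#'
#' @param results a [ebayes_moderate()] result.
#' @param lfc_cut log2-fold-change cutoff (strict).
#' @param p_cut p-value cutoff (strict).
#' @param use_adjusted select on BH-adjusted p instead of raw p.
#' @return list with `up` and `down` data.frames (ordered by p then
#'   feature_id) and `results`, the full table with `direction` filled in.
#' @export
select_differential <- function(results, lfc_cut = 0.5, p_cut = 0.05,
                                use_adjusted = FALSE) {
  stopifnot(inherits(results, "moderated_result"))
  pv <- if (use_adjusted) results$p_adj else results$p
  results$direction <- ifelse(pv < p_cut & results$logfc > lfc_cut, "up",
                       ifelse(pv < p_cut & results$logfc < -lfc_cut, "down", "ns"))
  ord <- order(pv, results$feature_id)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  list(up = results[results$direction == "up", , drop = FALSE],
       down = results[results$direction == "down", , drop = FALSE],
       results = results)
}
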