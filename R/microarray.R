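#' Detection calling and background subtraction
#'
#' A spot is considered a true signal when its raw intensity exceeds that
#' sample's background `noise_mean + k_sd * noise_sd`. Detected spots are
#' background-subtracted (`intensity - noise_mean`, floored at 0); undetected
#' spots become missing.
#'
#' @param raw an [expr_matrix()] of kind `raw_intensity`.
#' @param noise a [noise_stats()] table covering every sample in `raw`.
#' @param k_sd number of noise SDs above the noise mean required for
#'   detection (platform rule: 2).
#' @return a list of class `detection_result`: `mask` (logical feature x
#'   sample grid), `corrected` (`expr_matrix`, kind `raw_intensity`, missing
#'   where undetected), `detected_count_per_sample` (named integer vector).
#' @export
detection_call <- function(raw, noise, k_sd = 2) {
  check_kind(raw, "raw_intensity", "detection_call")
  stopifnot(inherits(noise, "noise_stats"))
  missing_noise <- setdiff(colnames(raw), noise$sample_id)
  if (length(missing_noise))
    stop("no noise record for sample(s): ", paste(missing_noise, collapse = ", "),
         call. = FALSE)
  idx <- match(colnames(raw), noise$sample_id)
  thresh <- noise$noise_mean[idx] + k_sd * noise$noise_sd[idx]
  bg <- noise$noise_mean[idx]
  v <- unclass(raw)
  mask <- sweep(v, 2, thresh, ">")
  mask[is.na(mask)] <- FALSE
  corrected <- sweep(v, 2, bg, "-")
  corrected[corrected < 0] <- 0
  corrected[!mask] <- NA_real_
  structure(list(
    mask = mask,
    corrected = expr_matrix(corrected, "raw_intensity"),
    detected_count_per_sample = colSums(mask)
  ), class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat("<detection_result>", nrow(x$mask), "features x", ncol(x$mask), "samples\n")
  cat("detected per sample:\n")
  print(x$detected_count_per_sample)
  invisible(x)
}

#' Sample quality control by detected-spot count
#'
#' Removes arrays on which fewer than `min_detected` features exceeded the
#' background threshold (the rule under which the original cohort lost two
#' arrays). The default requires 10% of all features.
#'
#' @param det a [detection_call()] result.
#' @param min_detected minimum detected-feature count to retain a sample;
#'   default `ceiling(0.1 * n_features)`.
#' @return list with `retained` (sample ids), `excluded` (data.frame
#'   `sample_id`, `detected_count`), `min_detected`, and `corrected`
#'   (the corrected matrix restricted to retained samples).
#' @export
qc_filter_samples <- function(det, min_detected = NULL) {
  stopifnot(inherits(det, "detection_result"))
  if (is.null(min_detected)) min_detected <- ceiling(0.1 * nrow(det$mask))
  if (min_detected < 0) stop("min_detected must be >= 0", call. = FALSE)
  counts <- det$detected_count_per_sample
  keep <- counts >= min_detected
  if (!any(keep))
    stop("all samples excluded at min_detected = ", min_detected,
         " (max detected count was ", max(counts), ")", call. = FALSE)
  list(
    retained = names(counts)[keep],
    excluded = data.frame(sample_id = names(counts)[!keep],
                          detected_count = unname(counts[!keep]),
                          stringsAsFactors = FALSE),
    min_detected = min_detected,
    corrected = det$corrected[, keep, drop = FALSE]
  )
}

#' Keep highly expressed features
#'
#' Retains features whose mean background-corrected intensity over non-missing
#' samples exceeds `mean_threshold` arbitrary units (the 80-AU rule that kept
#' 125 miRs in the original cohort). Alternatively `top_n` keeps the n
#' features with the largest means.
#'
#' @param mat `expr_matrix`, kind `raw_intensity` (corrected).
#' @param mean_threshold AU cutoff on the per-feature mean; strict `>`.
#' @param top_n if non-`NULL`, keep the `top_n` largest means instead.
#' @return the filtered `expr_matrix` with attribute `kept_count`.
#' @export
filter_top_expressed <- function(mat, mean_threshold = 80, top_n = NULL) {
  check_kind(mat, "raw_intensity", "filter_top_expressed")
  means <- rowMeans(mat, na.rm = TRUE)
  means[is.nan(means)] <- -Inf   # feature never detected
  if (is.null(top_n)) {
    keep <- means > mean_threshold
  } else {
    keep <- rank(-means, ties.method = "first") <= top_n
  }
  if (!any(keep))
    stop("no features retained: max mean ", signif(max(means), 4),
         " vs threshold ", mean_threshold, call. = FALSE)
  out <- mat[keep, , drop = FALSE]
  attr(out, "kept_count") <- sum(keep)
  out
}

#' Log2 transform intensities
#'
#' @param mat `expr_matrix`, kind `raw_intensity`.
#' @param offset added before the log to admit zero intensities (AU).
#' @return `expr_matrix` of kind `log2`; missing propagates.
#' @export
log2_transform <- function(mat, offset = 1) {
  check_kind(mat, "raw_intensity", "log2_transform")
  v <- unclass(mat)
  if (any(v + offset <= 0, na.rm = TRUE))
    stop("values + offset must be > 0 for log2 transform", call. = FALSE)
  expr_matrix(log2(v + offset), "log2")
}

#' Invert [log2_transform()]
#' @inheritParams log2_transform
#' @export
log2_inverse <- function(mat, offset = 1) {
  check_kind(mat, c("log2", "normalized_log2"), "log2_inverse")
  expr_matrix(pmax(2^unclass(mat) - offset, 0), "raw_intensity")
}

#' Cyclic loess normalization
#'
#' Pairwise MA-trend normalization on the log2 scale: for every unordered
#' sample pair (i, j), a locally weighted regression of M = x_i - x_j on
#' A = (x_i + x_j)/2 is fitted through the features complete in both samples;
#' half the fitted trend is subtracted from i and added to j, so each pair's
#' adjustments cancel exactly. The full sweep over pairs is repeated
#' `iterations` times.
#'
#' Features missing in one sample of a pair do not enter the fit but still
#' receive the adjustment predicted at their available abundance value;
#' fully missing cells stay missing.
#'
#' @param mat `expr_matrix`, kind `log2`, at least 2 samples.
#' @param span smoother span (fraction of points in each local window).
#' @param iterations number of full sweeps over all pairs.
#' @param min_points minimum complete features required to fit any pair.
#' @return `expr_matrix` of kind `normalized_log2`.
#' @export
cyclic_loess_normalize <- function(mat, span = 0.7, iterations = 3,
                                   min_points = 10) {
  check_kind(mat, "log2", "cyclic_loess_normalize")
  if (ncol(mat) < 2) stop("need >= 2 samples to normalize", call. = FALSE)
  x <- unclass(mat)
  n <- ncol(x)
  for (it in seq_len(iterations)) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        xi <- x[, i]; xj <- x[, j]
        both <- !is.na(xi) & !is.na(xj)
        if (sum(both) < min_points)
          stop(sprintf("pair (%s, %s): only %d complete features (< %d)",
                       colnames(x)[i], colnames(x)[j], sum(both), min_points),
               call. = FALSE)
        A <- (xi[both] + xj[both]) / 2
        M <- xi[both] - xj[both]
        fit <- stats::lowess(A, M, f = span)
        pred <- function(a) stats::approx(fit$x, fit$y, xout = a, rule = 2,
                                          ties = mean)$y
        adj <- pred(A) / 2
        x[both, i] <- xi[both] - adj
        x[both, j] <- xj[both] + adj
        only_i <- !is.na(xi) & is.na(xj)
        if (any(only_i)) x[only_i, i] <- xi[only_i] - pred(xi[only_i]) / 2
        only_j <- is.na(xi) & !is.na(xj)
        if (any(only_j)) x[only_j, j] <- xj[only_j] + pred(xj[only_j]) / 2
      }
    }
  }
  expr_matrix(x, "normalized_log2")
}

#' Run detection, QC, filtering, log2 and normalization in order
#'
#' Convenience wrapper enforcing the canonical stage order; each stage is also
#' available separately.
#'
#' @inheritParams detection_call
#' @inheritParams qc_filter_samples
#' @inheritParams filter_top_expressed
#' @inheritParams log2_transform
#' @inheritParams cyclic_loess_normalize
#' @return list: `normalized` (`expr_matrix`, kind `normalized_log2`),
#'   `qc` (the [qc_filter_samples()] report), `detection`, `kept_features`.
#' @export
normalize_microarray <- function(raw, noise, k_sd = 2, min_detected = NULL,
                                 mean_threshold = 80, top_n = NULL, offset = 1,
                                 span = 0.7, iterations = 3) {
  det <- detection_call(raw, noise, k_sd = k_sd)
  qc <- qc_filter_samples(det, min_detected = min_detected)
  kept <- filter_top_expressed(qc$corrected, mean_threshold = mean_threshold,
                               top_n = top_n)
  lg <- log2_transform(kept, offset = offset)
  norm <- cyclic_loess_normalize(lg, span = span, iterations = iterations)
  list(normalized = norm, qc = qc, detection = det,
       kept_features = rownames(kept))
}
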