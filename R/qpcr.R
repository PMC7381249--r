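#' Delta-delta-CT relative quantification
#'
#' For a target gene and its reference (GAPDH for mRNA, RNU6b for miR):
#' `dCT_s = CT_target,s - CT_ref,s`; `ddCT_s = dCT_s - summary(dCT over
#' calibrator samples)`; fold change `FC_s = 2^(-ddCT_s)`. Calibrators are
#' summarized by the arithmetic mean of dCT by default, or by the geometric
#' mean of fold changes (identical when there is one calibrator).
#'
#' @param ct `expr_matrix` of kind `ct` (targets in rows, samples in columns).
#' @param target target row name.
#' @param reference reference row name for this target's panel.
#' @param calibrator_samples sample ids forming the calibrator; the target
#'   and reference must be measured in at least one of them.
#' @param calibrator_summary `"mean_dct"` or `"geomean_fc"`.
#' @return named numeric vector of fold changes per sample; samples missing
#'   the target or reference CT get `NA` with a warning.
#' @export
delta_delta_ct <- function(ct, target, reference, calibrator_samples,
                           calibrator_summary = c("mean_dct", "geomean_fc")) {
  check_kind(ct, "ct", "delta_delta_ct")
  calibrator_summary <- match.arg(calibrator_summary)
  for (id in c(target, reference))
    if (!id %in% rownames(ct)) stop("target/reference '", id, "' not in CT table",
                                    call. = FALSE)
  missing_cal <- setdiff(calibrator_samples, colnames(ct))
  if (length(missing_cal))
    stop("calibrator sample(s) not in CT table: ",
         paste(missing_cal, collapse = ", "), call. = FALSE)
  dct <- unclass(ct)[target, ] - unclass(ct)[reference, ]
  cal <- dct[calibrator_samples]
  cal <- cal[!is.na(cal)]
  if (!length(cal))
    stop("no calibrator sample has both target and reference CT for ", target,
         call. = FALSE)
  # geometric mean of 2^-dct over calibrators equals 2^-mean(dct), so the two
  # summaries coincide; both retained for the config surface
  cal_dct <- mean(cal)
  fc <- 2^(-(dct - cal_dct))
  if (anyNA(fc))
    warning("missing CT for '", target, "' or '", reference, "' in sample(s): ",
            paste(names(fc)[is.na(fc)], collapse = ", "), call. = FALSE)
  fc
}

#' Fold changes for a whole panel
#'
#' Runs [delta_delta_ct()] for every panel analyte against its side's
#' reference and stacks the result into an `expr_matrix` of kind `rq`
#' (fold-change scale).
#'
#' @inheritParams delta_delta_ct
#' @param panel an [analyte_panel()].
#' @return `expr_matrix` (analytes x samples, kind `rq`).
#' @export
panel_fold_changes <- function(ct, panel, calibrator_samples,
                               calibrator_summary = c("mean_dct", "geomean_fc")) {
  stopifnot(inherits(panel, "analyte_panel"))
  calibrator_summary <- match.arg(calibrator_summary)
  rows <- lapply(c(stats::setNames(panel$mrna_ids, panel$mrna_ids),
                   stats::setNames(panel$mir_ids, panel$mir_ids)),
                 function(a) {
                   ref <- if (a %in% panel$mrna_ids) panel$mrna_reference else panel$mir_reference
                   delta_delta_ct(ct, a, ref, calibrator_samples, calibrator_summary)
                 })
  m <- do.call(rbind, rows)
  colnames(m) <- colnames(ct)
  expr_matrix(m, "rq")
}

#' Per-sample quantities on the 2^(-dCT) scale
#'
#' Expression of each target relative to its reference within the same
#' sample, with no calibrator: `2^(-(CT_target - CT_ref))`. This is the
#' within-sample quantity that [relative_quantity_to_median()] scales to the
#' cohort median.
#'
#' @inheritParams panel_fold_changes
#' @return `expr_matrix` (analytes x samples, kind `rq`).
#' @export
panel_dct_quantities <- function(ct, panel) {
  check_kind(ct, "ct", "panel_dct_quantities")
  stopifnot(inherits(panel, "analyte_panel"))
  analytes <- c(panel$mrna_ids, panel$mir_ids)
  refs <- c(rep(panel$mrna_reference, length(panel$mrna_ids)),
            rep(panel$mir_reference, length(panel$mir_ids)))
  missing_rows <- setdiff(unique(c(analytes, refs)), rownames(ct))
  if (length(missing_rows))
    stop("CT table missing row(s): ", paste(missing_rows, collapse = ", "),
         call. = FALSE)
  v <- unclass(ct)
  m <- 2^(-(v[analytes, , drop = FALSE] - v[refs, , drop = FALSE]))
  rownames(m) <- analytes
  expr_matrix(m, "rq")
}

#' Relative quantity to the cohort median
#'
#' Scales each analyte by its median over a reference sample scope
#' (typically the unstimulated control cultures): `RQ_s = value_s /
#' median(value over scope)`. Medians use non-missing scope values only; an
#' analyte with no non-missing scope value is dropped with a warning.
#'
#' @param values `expr_matrix` of kind `rq` (fold changes or 2^(-dCT)
#'   quantities), all scope values > 0.
#' @param sample_scope sample ids over which medians are taken (must be a
#'   subset of the matrix's samples); default all samples.
#' @return `expr_matrix` of kind `rq` with attribute
#'   `normalization_scope = "vs_cohort_median"` and attribute `scope_medians`.
#' @export
relative_quantity_to_median <- function(values, sample_scope = colnames(values)) {
  check_kind(values, "rq", "relative_quantity_to_median")
  missing_scope <- setdiff(sample_scope, colnames(values))
  if (length(missing_scope))
    stop("scope sample(s) not in matrix: ", paste(missing_scope, collapse = ", "),
         call. = FALSE)
  v <- unclass(values)
  med <- apply(v[, sample_scope, drop = FALSE], 1, stats::median, na.rm = TRUE)
  drop <- is.na(med)
  if (any(drop)) {
    warning("analyte(s) with no non-missing scope values dropped: ",
            paste(rownames(v)[drop], collapse = ", "), call. = FALSE)
    v <- v[!drop, , drop = FALSE]
    med <- med[!drop]
  }
  out <- expr_matrix(v / med, "rq")
  attr(out, "normalization_scope") <- "vs_cohort_median"
  attr(out, "scope_medians") <- med
  out
}
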