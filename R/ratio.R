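#' Per-sample mRNA/miR ratio over a panel
#'
#' For each sample, the median RQ over the panel's mRNAs divided by the
#' median RQ over its miRs. Requires RQ values normalized to the cohort
#' median ([relative_quantity_to_median()]); samples lacking any non-missing
#' value on either panel side are dropped with a warning.
#'
#' @param rq `expr_matrix` of kind `rq` with
#'   `normalization_scope = "vs_cohort_median"`.
#' @param panel an [analyte_panel()].
#' @return data.frame of class `ratio_results`: `sample_id`,
#'   `median_rq_mrna`, `median_rq_mir`, `ratio`, `group` (`NA` until
#'   [classify_ratio()]).
#' @export
mrna_mir_ratio <- function(rq, panel) {
  check_kind(rq, "rq", "mrna_mir_ratio")
  stopifnot(inherits(panel, "analyte_panel"))
  if (!identical(attr(rq, "normalization_scope"), "vs_cohort_median"))
    stop("rq must be normalized to the cohort median first ",
         "(relative_quantity_to_median)", call. = FALSE)
  v <- unclass(rq)
  mrna <- v[intersect(panel$mrna_ids, rownames(v)), , drop = FALSE]
  mir <- v[intersect(panel$mir_ids, rownames(v)), , drop = FALSE]
  if (!nrow(mrna) || !nrow(mir))
    stop("panel side absent from RQ matrix", call. = FALSE)
  med_mrna <- apply(mrna, 2, stats::median, na.rm = TRUE)
  med_mir <- apply(mir, 2, stats::median, na.rm = TRUE)
  drop <- is.na(med_mrna) | is.na(med_mir)
  if (any(drop))
    warning("sample(s) with an empty panel side dropped: ",
            paste(colnames(v)[drop], collapse = ", "), call. = FALSE)
  out <- data.frame(sample_id = colnames(v)[!drop],
                    median_rq_mrna = med_mrna[!drop],
                    median_rq_mir = med_mir[!drop],
                    ratio = med_mrna[!drop] / med_mir[!drop],
                    group = NA_character_, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ratio_results", "data.frame")
  out
}

#' Classify samples by mRNA/miR ratio
#'
#' Three groups with strict cutoffs: `high` when ratio > `hi_cut`, `low` when
#' ratio < `lo_cut`, otherwise `intermediate` (boundary values are
#' intermediate). The low cutoff defaults to the exact rational 2/3 (i.e.
#' 1/1.5), not a rounded decimal. Output is ordered by ratio descending.
#'
#' @param results a [mrna_mir_ratio()] result.
#' @param hi_cut,lo_cut cutoffs, `hi_cut > lo_cut > 0`.
#' @return the `ratio_results` with `group` filled, ordered by descending
#'   ratio; attribute `group_sizes` (named high/intermediate/low).
#' @export
classify_ratio <- function(results, hi_cut = 1.5, lo_cut = 2 / 3) {
  stopifnot(inherits(results, "ratio_results"))
  if (!(hi_cut > lo_cut && lo_cut > 0))
    stop("need hi_cut > lo_cut > 0", call. = FALSE)
  results$group <- ifelse(results$ratio > hi_cut, "high",
                   ifelse(results$ratio < lo_cut, "low", "intermediate"))
  results <- results[order(-results$ratio, results$sample_id), , drop = FALSE]
  rownames(results) <- NULL
  attr(results, "group_sizes") <- c(
    high = sum(results$group == "high"),
    intermediate = sum(results$group == "intermediate"),
    low = sum(results$group == "low"))
  results
}

#' Paired nicotine-response shift by control ratio group
#'
#' Pairs control and nicotine cultures by `pair_id`, freezes each pair's
#' group at the control condition, and tests the paired ratio differences
#' (nicotine - control) within each control group with the exact two-sided
#' Wilcoxon signed-rank test. When every pair in a group of size n moves the
#' same way the exact p is `2 / 2^n` (0.0078125 at n = 8, 0.03125 at n = 6).
#'
#' @param control,nicotine classified [classify_ratio()] results for the two
#'   conditions (sample ids as in `meta`).
#' @param meta [sample_table()] with `pair_id` and `condition` for every
#'   sample; unpaired samples are excluded with a warning.
#' @return data.frame of class `shift_summaries`, one row per control group:
#'   `group`, `n_pairs`, `decreased`, `increased`, `tied`, `statistic`, `p`,
#'   `method`; attribute `pairs` (per-pair data.frame with both ratios).
#' @export
nicotine_response_shift <- function(control, nicotine, meta) {
  stopifnot(inherits(control, "ratio_results"), inherits(nicotine, "ratio_results"))
  if (is.null(meta$pair_id)) stop("metadata has no pair_id column", call. = FALSE)
  ctrl_pair <- meta$pair_id[match(control$sample_id, meta$sample_id)]
  nic_pair <- meta$pair_id[match(nicotine$sample_id, meta$sample_id)]
  common <- intersect(ctrl_pair[!is.na(ctrl_pair)], nic_pair[!is.na(nic_pair)])
  unpaired <- c(control$sample_id[!ctrl_pair %in% common],
                nicotine$sample_id[!nic_pair %in% common])
  if (length(unpaired))
    warning("unpaired sample(s) excluded: ", paste(unpaired, collapse = ", "),
            call. = FALSE)
  ci <- match(common, ctrl_pair)
  ni <- match(common, nic_pair)
  pairs <- data.frame(pair_id = common,
                      group = control$group[ci],
                      ratio_control = control$ratio[ci],
                      ratio_nicotine = nicotine$ratio[ni],
                      stringsAsFactors = FALSE)
  pairs$diff <- pairs$ratio_nicotine - pairs$ratio_control
  out <- do.call(rbind, lapply(split(pairs, pairs$group), function(g) {
    tst <- wilcoxon_signed_rank(g$diff)
    data.frame(group = g$group[1], n_pairs = nrow(g),
               decreased = sum(g$diff < 0), increased = sum(g$diff > 0),
               tied = sum(g$diff == 0), statistic = tst$statistic,
               p = tst$p_two_sided, method = tst$method,
               stringsAsFactors = FALSE)
  }))
  ord <- match(c("high", "intermediate", "low"), out$group)
  out <- out[ord[!is.na(ord)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pairs") <- pairs
  class(out) <- c("shift_summaries", "data.frame")
  out
}
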