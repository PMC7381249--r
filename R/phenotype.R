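#' Naive-memory score configurations
#'
#' Two published variants of the median-threshold point score:
#' * variant `"A"` — markers CD27+ frequency, IL7R, FOXO1, TCF7; at least 2
#'   points call a naive-memory phenotype.
#' * variant `"B"` — markers IL7R, FOXO1, BCL6, TCF7; at least 3 points.
#'
#' @param variant `"A"`, `"B"`, or `"custom"`.
#' @param markers marker names (required for `"custom"`).
#' @param min_points minimum points for a naive-memory call (required for
#'   `"custom"`).
#' @return list of class `score_config` with `markers`, `min_points`,
#'   `variant_name`.
#' @export
score_config <- function(variant = c("A", "B", "custom"), markers = NULL,
                         min_points = NULL) {
  variant <- match.arg(variant)
  if (variant == "A") {
    markers <- markers %||% c("CD27_freq", "IL7R", "FOXO1", "TCF7")
    min_points <- min_points %||% 2L
  } else if (variant == "B") {
    markers <- markers %||% c("IL7R", "FOXO1", "BCL6", "TCF7")
    min_points <- min_points %||% 3L
  } else {
    if (is.null(markers) || is.null(min_points))
      stop("custom variant needs `markers` and `min_points`", call. = FALSE)
  }
  min_points <- as.integer(min_points)
  if (min_points < 1 || min_points > length(markers))
    stop("min_points must lie in 1..", length(markers), call. = FALSE)
  structure(list(markers = markers, min_points = min_points,
                 variant_name = variant), class = "score_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score the naive-memory phenotype
#'
#' One point per marker whose value is strictly greater than that marker's
#' median over the non-missing cohort values (ties at the median score 0, a
#' deliberate strict reading that can change calls). Missing marker values
#' score 0 and are flagged. Samples with at least `min_points` points are
#' labeled `naive_memory`, otherwise `effector`. Because only ranks matter,
#' scores are invariant to any strictly monotone per-marker transformation,
#' so mixed units (a protein frequency next to mRNA levels) are fine.
#'
#' @param markers `expr_matrix` (any kind), one row per marker.
#' @param config a [score_config()].
#' @param cohort sample ids over which medians are computed (>= 2); default
#'   all samples.
#' @return data.frame of class `phenotype_calls`: `sample_id`, `points`,
#'   `label`, `complete` (no missing markers), plus logical columns
#'   `above_median.<marker>`; attribute `medians`.
#' @export
score_naive_memory <- function(markers, config, cohort = colnames(markers)) {
  stopifnot(inherits(markers, "expr_matrix"), inherits(config, "score_config"))
  absent <- setdiff(config$markers, rownames(markers))
  if (length(absent))
    stop("config marker(s) absent from table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  missing_scope <- setdiff(cohort, colnames(markers))
  if (length(missing_scope))
    stop("cohort sample(s) not in table: ", paste(missing_scope, collapse = ", "),
         call. = FALSE)
  if (length(cohort) < 2) stop("need >= 2 cohort samples", call. = FALSE)
  v <- unclass(markers)[config$markers, cohort, drop = FALSE]
  med <- apply(v, 1, stats::median, na.rm = TRUE)
  above <- v > med          # strictly greater; NA where missing
  miss <- is.na(above)
  above[miss] <- FALSE
  points <- colSums(above)
  out <- data.frame(sample_id = cohort, points = as.integer(points),
                    label = ifelse(points >= config$min_points,
                                   "naive_memory", "effector"),
                    complete = colSums(miss) == 0,
                    stringsAsFactors = FALSE)
  flags <- as.data.frame(t(above))
  names(flags) <- paste0("above_median.", config$markers)
  out <- cbind(out, flags)
  rownames(out) <- NULL
  attr(out, "medians") <- med
  attr(out, "config") <- config
  class(out) <- c("phenotype_calls", "data.frame")
  out
}

#' Phenotype x smoking association
#'
#' Cross-tabulates the naive-memory/effector label against smoker status and
#' delegates to [odds_ratio()] and [fisher_exact()]. Samples with missing
#' label or smoker status are dropped with a warning.
#'
#' @param calls a [score_naive_memory()] result.
#' @param meta a [sample_table()] with smoker status for each called sample.
#' @return list: `table` ([table2x2()], rows naive_memory/effector, columns
#'   smoker yes/no), `odds_ratio`, `test` (Fisher `fx_test`).
#' @export
phenotype_smoking_association <- function(calls, meta) {
  stopifnot(inherits(calls, "phenotype_calls"))
  smoker <- meta$smoker[match(calls$sample_id, meta$sample_id)]
  keep <- !is.na(smoker) & !is.na(calls$label)
  if (any(!keep))
    warning("dropping sample(s) without smoker status or label: ",
            paste(calls$sample_id[!keep], collapse = ", "), call. = FALSE)
  lab <- calls$label[keep]; smk <- smoker[keep]
  t <- table2x2(sum(lab == "naive_memory" & smk),
                sum(lab == "naive_memory" & !smk),
                sum(lab == "effector" & smk),
                sum(lab == "effector" & !smk))
  list(table = t, odds_ratio = odds_ratio(t), test = fisher_exact(t))
}
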