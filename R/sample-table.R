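#' Sample metadata, noise statistics, and analyte panels
#'
#' @description
#' `sample_table()` validates per-sample metadata: `sample_id` (unique),
#' `diagnosis` (`RA`/`HC`), `smoker` (logical), `condition`
#' (`control`/`nicotine`), optional `pair_id` linking a donor's paired
#' control/nicotine cultures, optional `pooled_n` (number of donors pooled
#' into one array sample). Unknown columns are preserved untouched.
#'
#' @param df a data.frame with at least the required columns.
#' @return `df`, validated, with class `sample_table` prepended.
#' @export
sample_table <- function(df) {
  required <- c("sample_id", "diagnosis", "smoker", "condition")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("sample metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) stop("sample metadata has no rows", call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  df$diagnosis <- as.character(df$diagnosis)
  bad <- setdiff(unique(df$diagnosis), c("RA", "HC"))
  if (length(bad)) stop("invalid diagnosis value(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  df$smoker <- parse_yes_no(df$smoker, "smoker")
  df$condition <- as.character(df$condition)
  bad <- setdiff(unique(df$condition), c("control", "nicotine"))
  if (length(bad)) stop("invalid condition value(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.null(df$pair_id)) {
    df$pair_id <- as.character(df$pair_id)
    pid <- df$pair_id[!is.na(df$pair_id)]
    if (any(table(pid) > 2))
      stop("a pair_id occurs more than twice", call. = FALSE)
    key <- paste(df$pair_id, df$condition)[!is.na(df$pair_id)]
    if (anyDuplicated(key))
      stop("a pair_id occurs twice with the same condition", call. = FALSE)
  }
  if (!is.null(df$pooled_n)) {
    df$pooled_n <- as.integer(df$pooled_n)
    if (any(df$pooled_n < 1, na.rm = TRUE))
      stop("pooled_n must be >= 1", call. = FALSE)
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

parse_yes_no <- function(x, what) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("yes", "true", "1")] <- TRUE
  out[x %in% c("no", "false", "0")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stop("invalid ", what, " value(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  out
}

#' Read sample metadata from a delimited file
#'
#' @param path CSV or TSV with a header; required columns `sample_id`,
#'   `diagnosis`, `smoker`, `condition`.
#' @param sep separator, guessed from the extension when `NULL`.
#' @return a [sample_table()].
#' @export
read_sample_metadata <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (file.size(path) == 0) stop("empty metadata file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  sample_table(df)
}

#' Warn about samples present in metadata or matrix but not both
#'
#' @param mat an [expr_matrix()].
#' @param meta a [sample_table()].
#' @return character vector of unmatched ids (both directions), invisibly;
#'   a warning lists them when non-empty.
#' @export
check_sample_join <- function(mat, meta) {
  only_meta <- setdiff(meta$sample_id, colnames(mat))
  only_mat <- setdiff(colnames(mat), meta$sample_id)
  unmatched <- c(only_meta, only_mat)
  if (length(unmatched))
    warning("unmatched sample ids: ", paste(unmatched, collapse = ", "), call. = FALSE)
  invisible(unmatched)
}

#' Per-sample background-noise statistics
#'
#' One record per array sample: the mean and standard deviation of the
#' scanner's background noise in arbitrary units. The detection rule treats a
#' spot as true signal when its intensity exceeds `noise_mean + k_sd * noise_sd`.
#'
#' @param df data.frame with columns `sample_id`, `noise_mean`, `noise_sd`.
#' @return validated data.frame with class `noise_stats`.
#' @export
noise_stats <- function(df) {
  required <- c("sample_id", "noise_mean", "noise_sd")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("noise stats missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in noise stats", call. = FALSE)
  if (any(df$noise_mean < 0) || any(df$noise_sd < 0))
    stop("noise_mean and noise_sd must be >= 0", call. = FALSE)
  class(df) <- c("noise_stats", "data.frame")
  df
}

#' @rdname noise_stats
#' @param path TSV/CSV path.
#' @param sep separator, guessed from the extension when `NULL`.
#' @export
read_noise_stats <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  noise_stats(utils::read.table(path, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE))
}

#' qPCR analyte panels
#'
#' The mRNA and miR panels measured by qPCR, plus the reference target used to
#' normalize each side (GAPDH for mRNA, RNU6b for miR). Defaults are the
#' FOXO-pathway panel: mRNAs FOXO1, BCL6, IL7R, TCF7, PDCD1 and miRs
#' let-7c-5p, let-7d-5p, let-7e-5p, miR-92a-3p, miR-150-5p, miR-181a-5p.
#'
#' @param mrna_ids,mir_ids non-empty, disjoint character vectors.
#' @param mrna_reference,mir_reference reference targets; must not be panel
#'   members.
#' @return a list with class `analyte_panel`.
#' @export
analyte_panel <- function(mrna_ids = c("FOXO1", "BCL6", "IL7R", "TCF7", "PDCD1"),
                          mir_ids = c("let-7c-5p", "let-7d-5p", "let-7e-5p",
                                      "miR-92a-3p", "miR-150-5p", "miR-181a-5p"),
                          mrna_reference = "GAPDH",
                          mir_reference = "RNU6b") {
  if (!length(mrna_ids) || !length(mir_ids))
    stop("panels must be non-empty", call. = FALSE)
  if (length(intersect(mrna_ids, mir_ids)))
    stop("mRNA and miR panels must be disjoint", call. = FALSE)
  if (mrna_reference %in% c(mrna_ids, mir_ids) ||
      mir_reference %in% c(mrna_ids, mir_ids))
    stop("reference targets must not be panel members", call. = FALSE)
  structure(list(mrna_ids = mrna_ids, mir_ids = mir_ids,
                 mrna_reference = mrna_reference, mir_reference = mir_reference),
            class = "analyte_panel")
}
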