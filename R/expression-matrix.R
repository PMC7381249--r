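#' Expression matrices with a value-kind tag
#'
#' The package's canonical container is a plain numeric matrix (features in
#' rows, samples in columns, `NA` for missing) carrying a `value_kind`
#' attribute that records what the numbers mean. Stages refuse inputs whose
#' kind does not match their contract, which enforces the pipeline order
#' detection -> QC -> filter -> log2 -> loess -> DE.
#'
#' @param values numeric matrix with unique rownames (feature ids) and unique
#'   colnames (sample ids).
#' @param value_kind one of `"raw_intensity"`, `"log2"`, `"normalized_log2"`,
#'   `"ct"`, `"rq"`.
#' @return An object of class `expr_matrix`: the matrix plus its kind.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("f", 1:3), c("s1", "s2")))
#' em <- expr_matrix(m, "raw_intensity")
#' value_kind(em)
#' @export
expr_matrix <- function(values, value_kind) {
  value_kind <- match.arg(value_kind, VALUE_KINDS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  v <- values[!is.na(values)]
  if (value_kind == "raw_intensity" && any(v < 0))
    stop("raw_intensity values must be >= 0", call. = FALSE)
  if (value_kind == "ct" && (any(v <= 0) || any(v > 45)))
    stop("ct values must lie in (0, 45]", call. = FALSE)
  if (value_kind == "rq" && any(v <= 0))
    stop("rq values must be > 0", call. = FALSE)
  structure(values, value_kind = value_kind, class = c("expr_matrix", "matrix", "array"))
}

VALUE_KINDS <- c("raw_intensity", "log2", "normalized_log2", "ct", "rq")

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
value_kind <- function(x) attr(x, "value_kind")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples, value_kind = %s, %d missing\n",
              nrow(x), ncol(x), value_kind(x), sum(is.na(x))))
  if (nrow(x) <= 10 && ncol(x) <= 10) print(unclass(x)) else {
    cat("first corner:\n")
    print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))), drop = FALSE])
  }
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  kind <- value_kind(x)
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) out <- structure(out, value_kind = kind,
                                       class = c("expr_matrix", "matrix", "array"))
  out
}

#' @rdname expr_matrix
#' @export
feature_ids <- function(x) rownames(x)

#' @rdname expr_matrix
#' @export
sample_ids <- function(x) colnames(x)

# internal: assert a stage's kind contract
check_kind <- function(x, expected, stage) {
  if (!inherits(x, "expr_matrix"))
    stop(stage, ": input must be an expr_matrix", call. = FALSE)
  if (!value_kind(x) %in% expected)
    stop(sprintf("%s: value_kind '%s' not accepted (expected %s)",
                 stage, value_kind(x), paste(expected, collapse = "/")),
         call. = FALSE)
  invisible(x)
}

#' Read a delimited expression table
#'
#' Parses a TSV/CSV with one header row and one id column into an
#' [expr_matrix()], in features x samples orientation regardless of how the
#' file is laid out. Empty cells and `"NA"` become missing; the token `"X"`
#' (used for missing entries in some heatmap exports) is accepted only when
#' `allow_x = TRUE`, otherwise it is a parse error like any other non-numeric
#' cell.
#'
#' @param path file path.
#' @param value_kind the kind tag the values carry (see [expr_matrix()]).
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @param sep field separator; guessed from the extension when `NULL`
#'   (`.csv` -> comma, otherwise tab).
#' @param allow_x treat the token `"X"` as missing.
#' @return an `expr_matrix`.
#' @export
read_expression_table <- function(path, value_kind,
                                  orientation = c("features_in_rows", "samples_in_rows"),
                                  sep = NULL, allow_x = FALSE) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           check.names = FALSE, quote = "\"", comment.char = "")
  if (ncol(raw) < 2) stop("expression table needs an id column plus data columns", call. = FALSE)
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  cells <- as.matrix(raw[, -1, drop = FALSE])
  missing_tokens <- c("", "NA", if (allow_x) "X")
  is_missing <- is.na(cells) | cells %in% missing_tokens
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- !is_missing & is.na(num)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                 cells[w[1], w[2]], ids[w[1]], colnames(cells)[w[2]], path),
         call. = FALSE)
  }
  num[is_missing] <- NA_real_
  dimnames(num) <- list(ids, colnames(cells))
  if (orientation == "samples_in_rows") num <- t(num)
  expr_matrix(num, value_kind)
}

#' Write an expression table
#'
#' Plain-text inverse of [read_expression_table()]; round-trips values within
#' 1e-12 (full precision, `NA` for missing).
#'
#' @param x an `expr_matrix`.
#' @param path output path; `.csv` gives comma separation, anything else tab.
#' @param id_column header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, id_column = "feature_id") {
  stopifnot(inherits(x, "expr_matrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cells <- matrix(sprintf("%.17g", unclass(x)), nrow = nrow(x))
  cells[is.na(unclass(x))] <- NA
  df <- data.frame(rownames(x), cells, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(x))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
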