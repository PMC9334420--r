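#' Read a delimited score table
#'
#' Reads a CSV/TSV file with a header containing one binary activity
#' column and one or more numeric score columns, and validates it into a
#' [scored_dataset()]. Columns from lower-is-better methods (e.g. docking
#' energies) can be negated on input via `negate` so that the package-wide
#' "larger score = more active-like" convention holds.
#'
#' @param path file path; `.csv` is read comma-separated, anything else
#'   tab-separated unless `sep` is given.
#' @param activity_col name of the 0/1 activity column.
#' @param score_cols character vector of score column names; default all
#'   remaining columns except `id_col`.
#' @param negate character vector of score columns to multiply by -1.
#' @param id_col optional ligand id column to ignore.
#' @param sep field separator override.
#' @param na_action `"error"` (default) or `"drop"` rows with missing
#'   values (with a warning).
#' @return a [scored_dataset()].
#' @export
read_score_table <- function(path, activity_col = "activity",
                             score_cols = NULL, negate = character(),
                             id_col = NULL, sep = NULL,
                             na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!activity_col %in% names(df))
    stop("activity column '", activity_col, "' not found", call. = FALSE)
  if (is.null(score_cols))
    score_cols <- setdiff(names(df), c(activity_col, id_col))
  missing_cols <- setdiff(c(score_cols, negate), names(df))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  keep <- stats::complete.cases(df[, c(activity_col, score_cols)])
  if (!all(keep)) {
    if (na_action == "error")
      stop("missing values in rows: ",
           paste(utils::head(which(!keep), 10L), collapse = ", "),
           call. = FALSE)
    warning(sum(!keep), " rows with missing values dropped")
    df <- df[keep, , drop = FALSE]
  }
  act <- df[[activity_col]]
  if (!all(act %in% c(0, 1)))
    stop("activity column must contain only 0/1 values", call. = FALSE)
  sc <- as.matrix(df[, score_cols, drop = FALSE])
  if (!is.numeric(sc)) stop("score columns must be numeric", call. = FALSE)
  for (col in intersect(negate, score_cols))
    sc[, col] <- -sc[, col]
  scored_dataset(act, sc)
}

#' Write a scored dataset as a delimited table
#'
#' Inverse of [read_score_table()] (without negation): writes an
#' `activity` column followed by the score columns. `.csv` paths are
#' comma-separated, others tab-separated.
#'
#' @param data a [scored_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(data, path) {
  stopifnot(inherits(data, "scored_dataset"))
  sep <- if (grepl("\\.csv$", path, TRUE)) "," else "\t"
  df <- data.frame(activity = data$activity, data$scores,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
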