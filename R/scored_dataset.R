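#' Scored ligand collection
#'
#' Bundle a binary activity label with one or more real-valued score
#' columns, one per ranking method. All inference in the package consumes
#' this container. Scores follow the convention "larger is more
#' active-like"; columns from lower-is-better methods (e.g. docking
#' energies) must be negated first (see the `negate` argument of
#' [read_score_table()]).
#'
#' @param activity vector coercible to integer with values in \{0, 1\};
#'   1 marks an active ligand.
#' @param scores numeric vector, matrix, or data frame of scores; one
#'   column per method. Unnamed columns are named `alg1`, `alg2`, ...
#' @return An object of class `scored_dataset`: a list with elements
#'   `activity` (integer vector), `scores` (numeric matrix with column
#'   names), `n`, `n_active`, and `pi_hat` (observed active fraction).
#' @examples
#' d <- scored_dataset(c(1, 0, 1, 0), cbind(s1 = c(4, 3, 2, 1)))
#' d$pi_hat
#' @export
scored_dataset <- function(activity, scores) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (is.null(dim(scores))) {
    scores <- matrix(as.numeric(scores), ncol = 1L,
                     dimnames = list(NULL, "alg1"))
  }
  storage.mode(scores) <- "double"
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("alg", seq_len(ncol(scores)))
  }
  if (anyDuplicated(colnames(scores)))
    stop("duplicate score column names", call. = FALSE)
  if (is.logical(activity)) activity <- as.integer(activity)
  if (is.factor(activity)) activity <- as.integer(as.character(activity))
  activity <- as.integer(activity)
  n <- length(activity)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  if (nrow(scores) != n)
    stop("activity and scores must have the same length", call. = FALSE)
  if (anyNA(activity) || !all(activity %in% c(0L, 1L)))
    stop("activity must be binary (0/1)", call. = FALSE)
  if (!all(is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  structure(
    list(activity = activity, scores = scores, n = n,
         n_active = sum(activity), pi_hat = mean(activity)),
    class = "scored_dataset")
}

#' @export
print.scored_dataset <- function(x, ...) {
  cat(sprintf(
    "Scored dataset: %d ligands, %d active (pi_hat = %.4g)\nMethods: %s\n",
    x$n, x$n_active, x$pi_hat, paste(colnames(x$scores), collapse = ", ")))
  invisible(x)
}

# Fetch one score column, with a helpful error for unknown method names.
.method_scores <- function(data, method) {
  stopifnot(inherits(data, "scored_dataset"))
  if (length(method) != 1L)
    stop("exactly one method name expected", call. = FALSE)
  if (is.numeric(method)) {
    if (method < 1 || method > ncol(data$scores))
      stop("method index out of range", call. = FALSE)
    return(data$scores[, method])
  }
  if (!method %in% colnames(data$scores))
    stop(sprintf("unknown method '%s'; available: %s", method,
                 paste(colnames(data$scores), collapse = ", ")),
         call. = FALSE)
  data$scores[, method]
}

# Inference requires both classes to be present.
.check_both_classes <- function(data) {
  if (data$n_active < 1L)
    stop("at least one active ligand required", call. = FALSE)
  if (data$n_active > data$n - 1L)
    stop("at least one inactive ligand required", call. = FALSE)
  invisible(data)
}

#' Add a score column to a scored dataset
#'
#' @param data a [scored_dataset()].
#' @param name column name for the new method.
#' @param values numeric vector of length `data$n`.
#' @return a new `scored_dataset` with the extra column.
#' @export
add_score <- function(data, name, values) {
  stopifnot(inherits(data, "scored_dataset"))
  scored_dataset(data$activity,
                 cbind(data$scores,
                       matrix(as.numeric(values), ncol = 1,
                              dimnames = list(NULL, name))))
}

#' Consensus scores from several methods
#'
#' Combine score columns into a single consensus ranking. `"max-z"` takes
#' the elementwise maximum of the per-column z-scores (sample mean/SD);
#' `"min-rank"` takes the elementwise minimum of the per-column descending
#' ranks (rank 1 = best, average ranks for ties), negated so that larger
#' remains better.
#'
#' @param data a [scored_dataset()].
#' @param methods character vector of at least two method names.
#' @param kind `"max-z"` or `"min-rank"`.
#' @return numeric vector of consensus scores (larger = more active-like).
#' @export
consensus_score <- function(data, methods, kind = c("max-z", "min-rank")) {
  kind <- match.arg(kind)
  stopifnot(inherits(data, "scored_dataset"), length(methods) >= 2L)
  cols <- vapply(methods, function(m) .method_scores(data, m),
                 numeric(data$n))
  if (kind == "max-z") {
    z <- apply(cols, 2L, function(s) {
      sds <- sd(s)
      if (sds == 0) rep(0, length(s)) else (s - mean(s)) / sds
    })
    do.call(pmax, as.data.frame(z))
  } else {
    rk <- apply(cols, 2L, function(s) rank(-s, ties.method = "average"))
    -do.call(pmin, as.data.frame(rk))
  }
}
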