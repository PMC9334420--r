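#' Testing-fraction grids
#'
#' A grid of strictly increasing testing fractions in (0, 1]. Supply either
#' fractions directly or "number tested" counts, which convert as
#' r = count / n (deduplicated after conversion). Every fraction must
#' satisfy `r * n >= 1`, i.e. test at least one ligand.
#'
#' @param n library size the grid refers to.
#' @param fractions numeric vector of fractions in (0, 1].
#' @param counts integer vector of tested counts in `[1, n]`.
#' @return An object of class `testing_fraction_grid`: list with elements
#'   `fractions` (sorted, unique) and `n`.
#' @examples
#' testing_fraction_grid(1000, counts = c(2, 10, 100))
#' @export
testing_fraction_grid <- function(n, fractions = NULL, counts = NULL) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 1L)
  if (is.null(fractions) == is.null(counts))
    stop("supply exactly one of `fractions` or `counts`", call. = FALSE)
  if (!is.null(counts)) {
    if (any(!is.finite(counts)) || any(counts < 1) || any(counts > n))
      stop("counts must lie in [1, n]", call. = FALSE)
    fractions <- counts / n
  }
  if (any(!is.finite(fractions)) || any(fractions <= 0) ||
      any(fractions > 1))
    stop("fractions must lie in (0, 1]", call. = FALSE)
  fractions <- sort(unique(fractions))
  if (any(fractions * n < 1 - 1e-9))
    stop("every fraction must test at least one ligand (r * n >= 1)",
         call. = FALSE)
  structure(list(fractions = fractions, n = n),
            class = "testing_fraction_grid")
}

#' @export
print.testing_fraction_grid <- function(x, ...) {
  cat(sprintf("Testing-fraction grid: %d points on n = %d\n",
              length(x$fractions), x$n))
  print(utils::head(x$fractions, 10L))
  invisible(x)
}

#' Default tested-count grid
#'
#' The default grid used for confidence bands: tested counts
#' \{2^k, k=1..13\} union \{3^k, k=1..8\} union \{105, 300, 1500, 15000\},
#' intersected with `[1, n]` and converted to fractions. For
#' n >= 150,000 this yields 25 grid points spanning 2 to 15,000 tests.
#'
#' @param n library size.
#' @return a [testing_fraction_grid()].
#' @export
default_count_grid <- function(n) {
  counts <- sort(unique(c(2^(1:13), 3^(1:8), 105, 300, 1500, 15000)))
  counts <- counts[counts <= n]
  testing_fraction_grid(n, counts = counts)
}

# Normalise a grid argument (grid object or numeric fractions) to a
# validated fraction vector for a dataset of size n.
.as_fractions <- function(grid, n) {
  if (inherits(grid, "testing_fraction_grid")) {
    if (grid$n != n)
      stop("grid was built for a different library size", call. = FALSE)
    return(grid$fractions)
  }
  if (!is.numeric(grid) || length(grid) == 0L)
    stop("grid must be a testing_fraction_grid or a numeric vector",
         call. = FALSE)
  testing_fraction_grid(n, fractions = grid)$fractions
}
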