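#' Tie-safe score threshold for a testing fraction
#'
#' Returns the threshold \eqn{\hat t_r = \min\{t : \hat F(t) \ge 1 - r\}},
#' where \eqn{\hat F} is the empirical cdf of the scores. Restricting
#' candidate thresholds to observed score values makes tie handling
#' deterministic: a ligand is "tested" iff its score is strictly greater
#' than the threshold, so ligands tied at the threshold are never tested in
#' an arbitrary order. For `r = 1` the sentinel `-Inf` is returned so that
#' every ligand is tested.
#'
#' @param scores numeric vector of finite scores.
#' @param r testing fraction in (0, 1] with `r * length(scores) >= 1`.
#' @return a single threshold value (possibly `-Inf`).
#' @examples
#' threshold_at_fraction(1:5, 0.2)   # 4: only the top score is tested
#' threshold_at_fraction(rep(1, 4), 0.5)  # 1: all tied, none tested
#' @export
threshold_at_fraction <- function(scores, r) {
  n <- length(scores)
  if (n == 0L || !is.numeric(scores)) stop("scores must be a nonempty numeric vector", call. = FALSE)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (length(r) != 1L || !is.finite(r) || r <= 0 || r > 1)
    stop("invalid fraction: r must lie in (0, 1]", call. = FALSE)
  if (r * n < 1 - 1e-9)
    stop("invalid fraction: r * n < 1 tests no ligands", call. = FALSE)
  if (r == 1) return(-Inf)
  j <- ceiling(n * (1 - r) - 1e-9)
  j <- min(max(j, 1L), n)
  sort(scores, partial = j)[j]
}

# Thresholds, tested counts and active-tested counts for a whole vector of
# fractions at once; the O(n log n) workhorse behind the exported
# estimators. Fractions need not be sorted.
.curve_stats <- function(scores, activity, fractions) {
  n <- length(scores)
  s_sorted <- sort(scores)
  t_hat <- vapply(fractions, function(r) {
    if (r == 1) return(-Inf)
    j <- ceiling(n * (1 - r) - 1e-9)
    s_sorted[min(max(j, 1L), n)]
  }, numeric(1))
  Q <- vapply(t_hat, function(t) sum(activity[scores > t]), numeric(1))
  n_tested <- vapply(t_hat, function(t) sum(scores > t), numeric(1))
  list(t_hat = t_hat, Q = as.integer(Q), n_tested = as.integer(n_tested))
}

#' Estimated recall at one testing fraction
#'
#' Recall at fraction `r` is the proportion of active ligands whose score
#' exceeds the threshold \eqn{\hat t_r}:
#' \eqn{\hat\theta_r = Q_r / (n \hat\pi_+)} with
#' \eqn{Q_r = \sum_i X_i I(S_i > \hat t_r)}.
#'
#' @param data a [scored_dataset()] with at least one active ligand.
#' @param method score column name.
#' @param r testing fraction.
#' @return a list of class `recall_point` with elements `r`, `t_hat`, `Q`,
#'   `theta_hat`, and `n_tested`.
#' @export
recall_at_fraction <- function(data, method, r) {
  s <- .method_scores(data, method)
  if (data$n_active < 1L)
    stop("recall undefined without active ligands", call. = FALSE)
  st <- .curve_stats(s, data$activity, r)
  structure(list(r = r, t_hat = st$t_hat, Q = st$Q,
                 theta_hat = st$Q / data$n_active,
                 n_tested = st$n_tested, method = method),
            class = "recall_point")
}

#' @export
print.recall_point <- function(x, ...) {
  cat(sprintf("r = %g: t_hat = %g, tested %d, actives %d, recall = %.4g\n",
              x$r, x$t_hat, x$n_tested, x$Q, x$theta_hat))
  invisible(x)
}

#' Empirical hit enrichment curve
#'
#' Evaluates estimated recall over a grid of testing fractions. The curve
#' is non-decreasing in `r` and reaches 1 at `r = 1`.
#'
#' @param data a [scored_dataset()].
#' @param method score column name.
#' @param grid a [testing_fraction_grid()] or numeric vector of fractions.
#' @return a data frame of class `hit_enrichment_curve` with columns `r`,
#'   `t_hat`, `Q`, `n_tested`, `theta_hat`.
#' @examples
#' d <- scored_dataset(c(1, 0, 1, 0), c(4, 3, 2, 1))
#' hit_enrichment_curve(d, "alg1", c(0.25, 0.5, 1))
#' @export
hit_enrichment_curve <- function(data, method, grid) {
  .check_both_classes(data)
  fr <- .as_fractions(grid, data$n)
  s <- .method_scores(data, method)
  st <- .curve_stats(s, data$activity, fr)
  out <- data.frame(r = fr, t_hat = st$t_hat, Q = st$Q,
                    n_tested = st$n_tested,
                    theta_hat = st$Q / data$n_active)
  attr(out, "method") <- method
  attr(out, "n") <- data$n
  attr(out, "n_active") <- data$n_active
  class(out) <- c("hit_enrichment_curve", "data.frame")
  out
}

#' Enrichment factor curve
#'
#' The enrichment factor at fraction `r` is recall divided by the testing
#' fraction, \eqn{EF_r = \hat\theta_r / r}; values above 1 indicate better
#' than random early retrieval, and \eqn{EF_1 = 1}.
#'
#' @inheritParams hit_enrichment_curve
#' @return a data frame with columns `r`, `theta_hat`, `ef`.
#' @export
enrichment_factor_curve <- function(data, method, grid) {
  hec <- hit_enrichment_curve(data, method, grid)
  data.frame(r = hec$r, theta_hat = hec$theta_hat, ef = hec$theta_hat / hec$r)
}

#' Paired tested/not-tested counts for two methods
#'
#' The 2x2 frequency distribution of tested status of the active ligands
#' under two scoring methods, each at its own testing fraction: `Q1` and
#' `Q2` are the actives tested by each method, `Q12` the actives tested by
#' both, and `gamma_hat` the fraction of *all* ligands tested by both.
#' These counts drive McNemar/Wald/Bonett-Price inference and the
#' cross-method covariance estimators.
#'
#' @param data a [scored_dataset()].
#' @param method1,method2 score column names (may be equal).
#' @param r1 testing fraction for `method1`.
#' @param r2 testing fraction for `method2`; defaults to `r1`.
#' @return a list of class `paired_tested_counts` with elements `Q1`, `Q2`,
#'   `Q12`, `n_active`, `gamma_hat`, `r1`, `r2`, `t1`, `t2`, `n`, `pi_hat`.
#' @export
paired_tested_counts <- function(data, method1, method2, r1, r2 = r1) {
  .check_both_classes(data)
  s1 <- .method_scores(data, method1)
  s2 <- .method_scores(data, method2)
  t1 <- threshold_at_fraction(s1, r1)
  t2 <- threshold_at_fraction(s2, r2)
  tested1 <- s1 > t1
  tested2 <- s2 > t2
  act <- data$activity == 1L
  structure(list(
    Q1 = sum(tested1 & act), Q2 = sum(tested2 & act),
    Q12 = sum(tested1 & tested2 & act),
    n_active = data$n_active,
    gamma_hat = mean(tested1 & tested2),
    r1 = r1, r2 = r2, t1 = t1, t2 = t2,
    n = data$n, pi_hat = data$pi_hat,
    method1 = method1, method2 = method2),
    class = "paired_tested_counts")
}

#' @export
print.paired_tested_counts <- function(x, ...) {
  cat(sprintf(
    "Paired tested counts (r1 = %g, r2 = %g): Q1 = %d, Q2 = %d, Q12 = %d of %d actives; gamma_hat = %.4g\n",
    x$r1, x$r2, x$Q1, x$Q2, x$Q12, x$n_active, x$gamma_hat))
  invisible(x)
}
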