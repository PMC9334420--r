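## Pointwise two-method hypothesis tests and confidence intervals for the
## difference in recall at a testing fraction.

# Shared engine. Q1, Q2, Q12, gamma are paired tested counts at fraction r;
# m = number of actives; lambda1/lambda2 are only needed by the
# empirical-process procedures. The Bonett-Price "plus" shift adds one to
# each discordant count (Q_j + 1, total m + 2) before plugging into the
# chosen variance formula; pooling replaces both marginal recalls by their
# average inside the variance (joint terms are left alone).
.diff_inference <- function(Q1, Q2, Q12, gamma, m, n, r,
                            lambda1 = NULL, lambda2 = NULL,
                            procedure = "EmProc",
                            pooled = FALSE, plus = FALSE) {
  if (procedure == "McNemar") {
    disc <- Q1 + Q2 - 2 * Q12
    center <- (Q1 - Q2) / m
    se <- sqrt(max(disc, 0)) / m
    return(list(center = center, se = se, floored = FALSE))
  }
  shift <- if (plus) 1 else 0
  m_eff <- m + 2 * shift
  q1 <- Q1 + shift
  q2 <- Q2 + shift
  center <- (q1 - q2) / m_eff
  # coherent count shift: the pseudo-active also counts as tested, and
  # the two pseudo-ligands enlarge the library (keeps the Jiang-Zhao
  # bracket non-negative under the plus adjustment)
  n_eff <- n + 2 * shift
  pi_eff <- m_eff / n_eff
  r_eff <- min(max((r * n + shift) / n_eff, 0.5 / n_eff), 1)
  th1 <- q1 / m_eff
  th2 <- q2 / m_eff
  th12 <- Q12 / m_eff
  if (pooled) th1 <- th2 <- (th1 + th2) / 2
  if (procedure == "CorrBinom") {
    v <- (th1 * (1 - th1) + th2 * (1 - th2) -
            2 * (th12 - th1 * th2)) / m_eff
  } else {
    v1 <- as.numeric(var_jz(th1, lambda1, r_eff, n_eff, pi_eff))
    v2 <- as.numeric(var_jz(th2, lambda2, r_eff, n_eff, pi_eff))
    v <- if (procedure == "IndJZ") {
      v1 + v2
    } else {
      cv <- cov_emproc(th1, th2, th12, gamma, lambda1, lambda2,
                       r_eff, n_eff, pi_eff)
      v1 + v2 - 2 * cv
    }
  }
  list(center = center, se = sqrt(max(v, 0)), floored = v < 0)
}

#' McNemar test statistic for a recall difference
#'
#' \eqn{Z_r = (Q_1 - Q_2) / \sqrt{Q_1 + Q_2 - 2 Q_{12}}}: the classical
#' paired-proportions statistic applied to the tested/not-tested table of
#' the active ligands. Undefined (returned as `NA` with attribute
#' `degenerate = TRUE`) when the discordant count is zero.
#'
#' @param counts a [paired_tested_counts()].
#' @return numeric Z statistic.
#' @examples
#' d <- scored_dataset(c(1, 1, 0, 0), cbind(a = c(4, 3, 2, 1),
#'                                          b = c(1, 2, 3, 4)))
#' mcnemar_z(paired_tested_counts(d, "a", "b", 0.5))
#' @export
mcnemar_z <- function(counts) {
  stopifnot(inherits(counts, "paired_tested_counts"))
  disc <- counts$Q1 + counts$Q2 - 2 * counts$Q12
  if (disc <= 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  (counts$Q1 - counts$Q2) / sqrt(disc)
}

#' Wald confidence interval for a recall difference
#'
#' The unadjusted Wald interval for \eqn{\theta_1 - \theta_2} from the
#' paired tested counts, with standard error
#' \eqn{\sqrt{Q_1 + Q_2 - 2Q_{12} - (Q_1-Q_2)^2/(n\hat\pi_+)}
#'   / (n\hat\pi_+)}.
#'
#' @param counts a [paired_tested_counts()].
#' @param alpha two-sided error level (default 0.05).
#' @return length-2 vector `(lower, upper)`, with attributes `center`,
#'   `se`, and `degenerate` (TRUE when the SE collapses to 0).
#' @export
wald_interval <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "paired_tested_counts"))
  m <- counts$n_active
  disc <- counts$Q1 + counts$Q2 - 2 * counts$Q12
  dQ <- counts$Q1 - counts$Q2
  center <- dQ / m
  se <- sqrt(max(disc - dQ^2 / m, 0)) / m
  z <- qnorm(1 - alpha / 2)
  structure(c(lower = center - z * se, upper = center + z * se),
            center = center, se = se, degenerate = se == 0)
}

#' Bonett-Price plus-adjusted interval for a recall difference
#'
#' Adds one to each discordant count of the paired 2x2 table (so one to
#' each marginal count and two to the total) before applying the Wald
#' construction, giving center \eqn{(Q_1 - Q_2)/(n\hat\pi_+ + 2)} and
#' variance \eqn{[(Q_1 + Q_2 - 2Q_{12} + 2) -
#'   (Q_1 - Q_2)^2/(n\hat\pi_+ + 2)] / (n\hat\pi_+ + 2)^2}.
#' The "+2" keeps the width strictly positive even when all counts agree,
#' which is what rescues coverage at very small tested counts.
#'
#' @inheritParams wald_interval
#' @return length-2 vector `(lower, upper)` with attributes `center`, `se`.
#' @export
bonett_price_interval <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "paired_tested_counts"))
  m2 <- counts$n_active + 2
  disc2 <- counts$Q1 + counts$Q2 - 2 * counts$Q12 + 2
  dQ <- counts$Q1 - counts$Q2
  center <- dQ / m2
  se <- sqrt(max(disc2 - dQ^2 / m2, 0)) / m2
  z <- qnorm(1 - alpha / 2)
  structure(c(lower = center - z * se, upper = center + z * se),
            center = center, se = se, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p-values,
#' returned in input order. Thin wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Compare recall of two scoring methods at one testing fraction
#'
#' Tests \eqn{H_0: \theta_{1r} = \theta_{2r}} and builds a confidence
#' interval for the difference, using one of four procedures:
#' \describe{
#'   \item{EmProc}{empirical-process variance accounting for correlation
#'     both within each method (threshold estimation) and between methods
#'     (shared ligands); the recommended test.}
#'   \item{IndJZ}{treats the two methods as independent; each variance
#'     still corrects for threshold estimation. Conservative when scores
#'     are positively correlated.}
#'   \item{CorrBinom}{correlated-binomial variance ignoring threshold
#'     estimation.}
#'   \item{McNemar}{classical paired-proportions test on the discordant
#'     counts; its interval is the Bonett-Price plus interval. Identical
#'     to pooled, non-plus CorrBinom.}
#' }
#' `pooled = TRUE` substitutes the average recall for both marginal
#' recalls inside the variance (tests only). `plus = TRUE` applies the
#' Bonett-Price count shift to the plug-in estimates (recommended for
#' intervals); for CorrBinom this reproduces the Bonett-Price interval
#' exactly. With `plus`, the interval is centred at the shifted difference
#' \eqn{(Q_1 - Q_2)/(n\hat\pi_+ + 2)}.
#'
#' @param data a [scored_dataset()].
#' @param method1,method2 score column names.
#' @param r testing fraction.
#' @param procedure one of `"EmProc"`, `"IndJZ"`, `"CorrBinom"`,
#'   `"McNemar"`.
#' @param pooled pool the marginal recalls in the variance (tests only).
#' @param plus apply the Bonett-Price count shift.
#' @param alpha two-sided level for the interval (default 0.05).
#' @param bandwidth optional kernel bandwidth for the threshold-specific
#'   activity rate (EmProc/IndJZ only).
#' @return one-row data frame of class `comparison_result` with columns
#'   `method1`, `method2`, `r`, `diff`, `se`, `z`, `p_raw`, `p_adj`
#'   (`NA` outside a family), `ci_lower`, `ci_upper`, `procedure`,
#'   `pooled`, `plus`, `degenerate`.
#' @examples
#' d <- scored_dataset(rbinom(500, 1, 0.1),
#'                     cbind(a = rnorm(500), b = rnorm(500)))
#' compare_recall(d, "a", "b", r = 0.1)
#' @export
compare_recall <- function(data, method1, method2, r,
                           procedure = c("EmProc", "IndJZ", "CorrBinom",
                                         "McNemar"),
                           pooled = FALSE, plus = FALSE, alpha = 0.05,
                           bandwidth = NULL) {
  procedure <- match.arg(procedure)
  pc <- paired_tested_counts(data, method1, method2, r, r)
  m <- pc$n_active
  lam1 <- lam2 <- NULL
  if (procedure %in% c("EmProc", "IndJZ")) {
    lam1 <- estimate_lambda(data, method1, pc$t1, bandwidth)$value
    lam2 <- estimate_lambda(data, method2, pc$t2, bandwidth)$value
  }
  inf <- .diff_inference(pc$Q1, pc$Q2, pc$Q12, pc$gamma_hat, m, pc$n, r,
                         lam1, lam2, procedure, pooled, plus)
  diff <- (pc$Q1 - pc$Q2) / m
  degenerate <- !is.finite(inf$se) || inf$se == 0
  if (degenerate) {
    z <- NA_real_
    p <- if (inf$center == 0) 1 else NA_real_
  } else {
    z <- inf$center / inf$se
    p <- 2 * pnorm(-abs(z))
  }
  if (procedure == "McNemar") {
    ci <- bonett_price_interval(pc, alpha)
  } else if (degenerate) {
    ci <- c(NA_real_, NA_real_)
  } else {
    zq <- qnorm(1 - alpha / 2)
    ci <- c(inf$center - zq * inf$se, inf$center + zq * inf$se)
  }
  out <- data.frame(
    method1 = method1, method2 = method2, r = r,
    diff = diff, se = inf$se, z = z, p_raw = p, p_adj = NA_real_,
    ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
    procedure = procedure, pooled = pooled, plus = plus,
    degenerate = degenerate, stringsAsFactors = FALSE)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' All pairwise comparisons over a family of fractions
#'
#' Runs [compare_recall()] for every (method pair) x (fraction)
#' combination and applies a Benjamini-Hochberg adjustment across the full
#' family for the chosen procedure.
#'
#' @param data a [scored_dataset()].
#' @param pairs list of length-2 character vectors of method names, or a
#'   two-column character matrix.
#' @param fractions numeric vector of testing fractions.
#' @inheritParams compare_recall
#' @return data frame with one row per comparison; `p_adj` holds the
#'   BH-adjusted p-values over the whole family.
#' @export
compare_table <- function(data, pairs, fractions,
                          procedure = c("EmProc", "IndJZ", "CorrBinom",
                                        "McNemar"),
                          pooled = FALSE, plus = FALSE, alpha = 0.05,
                          bandwidth = NULL) {
  procedure <- match.arg(procedure)
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  rows <- list()
  for (pr in pairs) {
    for (r in fractions) {
      rows[[length(rows) + 1L]] <-
        compare_recall(data, pr[[1]], pr[[2]], r, procedure,
                       pooled, plus, alpha, bandwidth)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  class(out) <- c("comparison_result", "data.frame")
  out
}
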