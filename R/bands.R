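## Simultaneous confidence bands for hit enrichment curves and for the
## difference of two curves.

# Symmetrize and clip negative eigenvalues to zero. Plug-in covariance
# matrices need not be PSD; the repair is flagged so callers can log it.
.repair_psd <- function(V) {
  V <- (V + t(V)) / 2
  tol <- 1e-10 * max(1, max(abs(diag(V))))
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) >= -tol) {
    return(list(V = V, repaired = FALSE))
  }
  lam <- pmax(e$values, 0)
  list(V = e$vectors %*% (lam * t(e$vectors)), repaired = TRUE)
}

# Recall vector and within-curve covariance matrix for one method over
# ascending fractions. qshift/mshift implement the plus adjustments
# *inside the variance plug-ins*: (2, 4) = "add two successes, add two
# failures" for single-curve bands, (1, 2) = Bonett-Price shift for
# difference bands. The returned center `theta` is the unshifted recall
# estimate; shifting the center itself would bias it by several standard
# errors at very small tested counts. Lambda estimates are never shifted.
.single_cov <- function(data, method, fractions, plus = FALSE,
                        qshift = if (plus) 2 else 0,
                        mshift = if (plus) 4 else 0,
                        bandwidth = NULL) {
  s <- .method_scores(data, method)
  act <- data$activity
  n <- data$n
  m <- data$n_active
  st <- .curve_stats(s, act, fractions)
  # Coherent count shift: the qshift pseudo-actives enter the tested
  # count and the mshift pseudo-ligands enter the library size as well,
  # so that every plug-in (theta, r, pi) describes the same shifted
  # table. This keeps the Jiang-Zhao bracket >= (1 - Lambda)^2 >= 0, so
  # plus-adjusted variances can never go negative.
  m_eff <- m + mshift
  n_eff <- n + mshift
  pi_eff <- m_eff / n_eff
  r_eff <- pmin(pmax((st$n_tested + qshift) / n_eff, 0.5 / n_eff), 1)
  theta_center <- st$Q / m
  theta <- (st$Q + qshift) / m_eff
  h <- if (is.null(bandwidth)) .rot_bandwidth(s) else bandwidth
  lam <- vapply(st$t_hat, function(t) {
    if (is.infinite(t)) return(0)
    v <- .nw_lambda(s, act, t, h)
    if (is.na(v)) m / n else v
  }, numeric(1))
  k <- length(fractions)
  V <- matrix(0, k, k)
  for (i in seq_len(k)) {
    V[i, i] <- as.numeric(var_jz(theta[i], lam[i], r_eff[i], n_eff,
                                 pi_eff))
    if (i < k) {
      for (j in (i + 1):k) {
        V[i, j] <- V[j, i] <- cov_within_curve(
          theta[i], theta[j], lam[i], lam[j],
          r_eff[i], r_eff[j], n_eff, pi_eff)
      }
    }
  }
  rp <- .repair_psd(V)
  list(theta = theta_center, theta_var = theta, V = rp$V,
       repaired = rp$repaired, t_hat = st$t_hat, Q = st$Q, lambda = lam,
       m_eff = m_eff, r_eff = r_eff, n_eff = n_eff, s = s)
}

# Difference-curve covariance: within-curve matrices for both methods plus
# the two cross-method cross-fraction terms.
.diff_cov <- function(data, method1, method2, fractions, plus = FALSE,
                      bandwidth = NULL) {
  qs <- if (plus) 1 else 0
  ms <- if (plus) 2 else 0
  c1 <- .single_cov(data, method1, fractions, qshift = qs, mshift = ms,
                    bandwidth = bandwidth)
  c2 <- .single_cov(data, method2, fractions, qshift = qs, mshift = ms,
                    bandwidth = bandwidth)
  n <- data$n
  m_eff <- data$n_active + ms
  n_eff <- n + ms
  pi_eff <- m_eff / n_eff
  k <- length(fractions)
  T1 <- vapply(c1$t_hat, function(t) c1$s > t, logical(n)) * 1
  T2 <- vapply(c2$t_hat, function(t) c2$s > t, logical(n)) * 1
  act <- data$activity == 1L
  Q12 <- crossprod(T1[act, , drop = FALSE], T2[act, , drop = FALSE])
  G12 <- crossprod(T1, T2) / n
  C12 <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      C12[i, j] <- cov_cross_alg_frac(
        c1$theta_var[i], c2$theta_var[j], Q12[i, j] / m_eff, G12[i, j],
        c1$lambda[i], c2$lambda[j], c1$r_eff[i], c2$r_eff[j],
        n_eff, pi_eff)
    }
  }
  V <- c1$V + c2$V - C12 - t(C12)
  rp <- .repair_psd(V)
  # Bonett-Price style center: the symmetric +1 shift only shrinks the
  # difference slightly, so (Q1 - Q2)/(m + 2) is used when plus = TRUE.
  list(theta = (c1$Q - c2$Q) / m_eff, V = rp$V,
       repaired = rp$repaired || c1$repaired || c2$repaired,
       m_eff = m_eff)
}

#' Covariance of a recall vector along one curve
#'
#' Assembles the estimated covariance matrix of
#' \eqn{(\hat\theta_{r_1}, ..., \hat\theta_{r_k})} for a single method:
#' Jiang-Zhao variances on the diagonal and within-curve empirical-process
#' covariances off the diagonal, with plug-in recall and kernel-regression
#' activity-rate estimates. The matrix is symmetrised and, if needed,
#' eigenvalue-clipped to positive semidefiniteness (flagged in
#' `repaired`).
#'
#' @param data a [scored_dataset()].
#' @param method score column name.
#' @param grid a [testing_fraction_grid()] or numeric fraction vector.
#' @param plus apply the add-two-successes/add-two-failures shift to the
#'   recall plug-ins (`theta = (Q+2)/(n pi + 4)`).
#' @param bandwidth optional kernel bandwidth for the activity-rate
#'   regression.
#' @return object of class `curve_covariance`: `fractions`, `theta_hat`,
#'   `V`, `repaired`, `t_hat`, `Q`, `lambda`, `n`, `m_eff`, `plus`.
#' @export
curve_covariance <- function(data, method, grid, plus = FALSE,
                             bandwidth = NULL) {
  .check_both_classes(data)
  fr <- .as_fractions(grid, data$n)
  cc <- .single_cov(data, method, fr, plus = plus, bandwidth = bandwidth)
  structure(list(fractions = fr, theta_hat = cc$theta,
                 theta_var = cc$theta_var, V = cc$V,
                 repaired = cc$repaired, t_hat = cc$t_hat, Q = cc$Q,
                 lambda = cc$lambda, n = data$n, m_eff = cc$m_eff,
                 r_eff = cc$r_eff, n_eff = cc$n_eff,
                 plus = plus, method = method),
            class = "curve_covariance")
}

#' Covariance of the difference of two recall curves
#'
#' Covariance matrix of \eqn{\hat\theta_1(r) - \hat\theta_2(r)} over a
#' fraction grid: the two within-curve matrices minus both cross-method
#' cross-fraction covariance terms.
#'
#' @inheritParams curve_covariance
#' @param method1,method2 score column names.
#' @param plus apply the Bonett-Price count shift to the plug-ins.
#' @return object of class `curve_covariance` whose `theta_hat` is the
#'   difference vector.
#' @export
curve_covariance_diff <- function(data, method1, method2, grid,
                                  plus = FALSE, bandwidth = NULL) {
  .check_both_classes(data)
  fr <- .as_fractions(grid, data$n)
  cc <- .diff_cov(data, method1, method2, fr, plus = plus,
                  bandwidth = bandwidth)
  structure(list(fractions = fr, theta_hat = cc$theta, V = cc$V,
                 repaired = cc$repaired, n = data$n, m_eff = cc$m_eff,
                 plus = plus, method = c(method1, method2)),
            class = "curve_covariance")
}

#' @export
print.curve_covariance <- function(x, ...) {
  cat(sprintf("Curve covariance (%s): %d grid points%s%s\n",
              paste(x$method, collapse = " - "), length(x$fractions),
              if (x$plus) ", plus-adjusted" else "",
              if (x$repaired) ", PSD-repaired" else ""))
  invisible(x)
}

#' sup-t critical multiplier
#'
#' Monte-Carlo estimate of the \eqn{(1-\alpha)} quantile of
#' \eqn{\max_i |Z_i|}, where \eqn{Z} is zero-mean multivariate normal with
#' the correlation matrix implied by `V`. This is the smallest multiplier
#' `q` such that the rectanguloid
#' \eqn{\hat\theta_i \pm q\,SE(\hat\theta_i)} retains simultaneous
#' \eqn{1-\alpha} coverage (the statistic is scale invariant, so only the
#' correlation matters). Grid points with zero variance carry no
#' information about the max and are dropped (recorded in attribute
#' `dropped`).
#'
#' @param V covariance matrix or a [curve_covariance()] object.
#' @param alpha simultaneous error level.
#' @param draws Monte-Carlo sample size (at least 10^4; default 10^5).
#' @param seed optional integer seed; identical seed and draws give an
#'   identical q.
#' @return numeric critical value with attributes `dropped` and `draws`.
#' @export
supt_critical <- function(V, alpha = 0.05, draws = 1e5, seed = NULL) {
  if (inherits(V, "curve_covariance")) V <- V$V
  stopifnot(is.matrix(V), nrow(V) == ncol(V), alpha > 0, alpha < 1)
  if (draws < 1e4) stop("draws must be at least 10^4", call. = FALSE)
  d <- diag(V)
  keep <- is.finite(d) & d > 0
  if (!any(keep))
    stop("all grid points have zero variance; no sup-t critical value",
         call. = FALSE)
  C <- .repair_psd(cov2cor(V[keep, keep, drop = FALSE]))$V
  e <- eigen(C, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = nrow(C))
  q <- with_seed(seed, {
    Z <- matrix(rnorm(draws * nrow(C)), draws) %*% t(A)
    mx <- abs(Z[, 1])
    for (j in seq_len(ncol(Z))[-1]) mx <- pmax(mx, abs(Z[, j]))
    quantile(mx, 1 - alpha, names = FALSE)
  })
  structure(q, dropped = which(!keep), draws = draws)
}

#' Bonferroni critical multiplier
#'
#' \eqn{q = \sqrt{\chi^2_{1, 1-\alpha/k}}}, i.e. the normal quantile at
#' \eqn{\alpha/(2k)}; rectanguloid but conservative for correlated grids.
#'
#' @param k number of grid points.
#' @param alpha simultaneous error level.
#' @return numeric critical value.
#' @export
bonferroni_critical <- function(k, alpha = 0.05) {
  stopifnot(k >= 1, alpha > 0, alpha < 1)
  sqrt(qchisq(1 - alpha / k, df = 1))
}

#' Theta-projection critical multiplier
#'
#' \eqn{q = \sqrt{\chi^2_{k, 1-\alpha}}}: the smallest rectanguloid
#' containing the Wald confidence ellipsoid. Always at least as wide as
#' Bonferroni, so mainly of theoretical interest.
#'
#' @inheritParams bonferroni_critical
#' @return numeric critical value.
#' @export
theta_projection_critical <- function(k, alpha = 0.05) {
  stopifnot(k >= 1, alpha > 0, alpha < 1)
  sqrt(qchisq(1 - alpha, df = k))
}

.band_q <- function(V, band_type, alpha, draws, seed, k) {
  switch(band_type,
         "sup-t" = supt_critical(V, alpha, draws, seed),
         "bonferroni" = bonferroni_critical(k, alpha),
         "theta-projection" = theta_projection_critical(k, alpha))
}

.make_band <- function(cc, band_type, plus, alpha, draws, seed,
                       clip_lo, clip_hi) {
  se <- sqrt(pmax(diag(cc$V), 0))
  k <- length(cc$fractions)
  degenerate <- all(se == 0)
  if (degenerate) {
    q <- NA_real_
  } else {
    q <- .band_q(cc$V, band_type, alpha, draws, seed, k)
  }
  half <- if (degenerate) 0 else as.numeric(q) * se
  tab <- data.frame(
    r = cc$fractions,
    count = as.integer(round(cc$fractions * cc$n)),
    center = cc$theta_hat, se = se,
    lower = pmin(pmax(cc$theta_hat - half, clip_lo), clip_hi),
    upper = pmin(pmax(cc$theta_hat + half, clip_lo), clip_hi))
  structure(list(table = tab, q = as.numeric(q), band_type = band_type,
                 plus = plus, alpha = alpha,
                 mc_draws = if (band_type == "sup-t") draws else NA,
                 seed = seed, zero_variance = which(se == 0),
                 repaired = cc$repaired, degenerate = degenerate,
                 method = cc$method, n = cc$n),
            class = "enrichment_band")
}

#' Simultaneous confidence band for one hit enrichment curve
#'
#' Builds a rectanguloid band \eqn{\tilde\theta_i \pm q\,SE_i} over a
#' fraction grid with simultaneous level \eqn{1-\alpha}, using the sup-t
#' (default), Bonferroni, or theta-projection critical value. With
#' `plus = TRUE` (recommended) the recall plug-ins are shifted by the
#' add-two-successes/add-two-failures rule, which keeps every grid point
#' away from the degenerate 0/1 boundary and markedly improves small-count
#' coverage. Envelopes are clipped to `[0, 1]`.
#'
#' @inheritParams curve_covariance
#' @param grid grid of fractions; defaults to [default_count_grid()].
#' @param band_type `"sup-t"`, `"bonferroni"`, or `"theta-projection"`.
#' @param alpha simultaneous error level.
#' @param draws sup-t Monte-Carlo draws.
#' @param seed optional seed for the sup-t draw.
#' @return object of class `enrichment_band`: `table` (data frame with
#'   `r`, `count`, `center`, `se`, `lower`, `upper`), the critical value
#'   `q`, and construction metadata.
#' @export
confidence_band <- function(data, method, grid = NULL,
                            band_type = c("sup-t", "bonferroni",
                                          "theta-projection"),
                            plus = TRUE, alpha = 0.05, draws = 1e5,
                            seed = NULL, bandwidth = NULL) {
  band_type <- match.arg(band_type)
  if (is.null(grid)) grid <- default_count_grid(data$n)
  cc <- curve_covariance(data, method, grid, plus = plus,
                         bandwidth = bandwidth)
  .make_band(cc, band_type, plus, alpha, draws, seed, 0, 1)
}

#' Simultaneous confidence band for the difference of two curves
#'
#' As [confidence_band()], for \eqn{\hat\theta_1(r) - \hat\theta_2(r)}
#' with the difference-curve covariance (within-curve terms for both
#' methods minus the two cross-method terms). `plus = TRUE` applies the
#' Bonett-Price count shift. Envelopes are clipped to `[-1, 1]`. If the
#' two methods are identical the band degenerates to zero width and is
#' flagged.
#'
#' @inheritParams confidence_band
#' @param method1,method2 score column names.
#' @return object of class `enrichment_band`.
#' @export
confidence_band_diff <- function(data, method1, method2, grid = NULL,
                                 band_type = c("sup-t", "bonferroni",
                                               "theta-projection"),
                                 plus = TRUE, alpha = 0.05, draws = 1e5,
                                 seed = NULL, bandwidth = NULL) {
  band_type <- match.arg(band_type)
  if (is.null(grid)) grid <- default_count_grid(data$n)
  cc <- curve_covariance_diff(data, method1, method2, grid, plus = plus,
                              bandwidth = bandwidth)
  .make_band(cc, band_type, plus, alpha, draws, seed, -1, 1)
}

#' @export
print.enrichment_band <- function(x, ...) {
  cat(sprintf(
    "%s%s band (%s), alpha = %g, q = %.4g, %d grid points%s\n",
    if (x$plus) "plus-adjusted " else "", x$band_type,
    paste(x$method, collapse = " - "), x$alpha, x$q, nrow(x$table),
    if (x$degenerate) " [degenerate: zero-width]" else ""))
  print(utils::head(x$table, 8L))
  if (nrow(x$table) > 8L) cat("...\n")
  invisible(x)
}
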