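## Variance and covariance estimators for recall estimates.
##
## All covariance expressions are evaluated in expanded (cancelled) form so
## that theta12 = theta1 * theta2 causes no 0/0; the factored textbook
## forms are used only in tests where they are defined. Variances are
## floored at zero (plug-in Lambda estimates can push the raw value
## negative); the flooring is flagged.

# Bare-metal Nadaraya-Watson regression of activity on score at a single
# point, Gaussian kernel. Returns NA when the kernel mass underflows.
# The bandwidth is floored so that the kernel window reaches at least
# `min_neighbors` observations: in the sparse extreme tail a fixed
# rule-of-thumb bandwidth can leave the estimate driven by two or three
# (mostly active) ligands, producing spikes near 1 that collapse the
# Jiang-Zhao variance bracket.
.nw_lambda <- function(scores, activity, t, h, min_neighbors = 20L) {
  K <- min(min_neighbors, length(scores))
  if (K >= 1L) {
    d <- abs(scores - t)
    h <- max(h, sort(d, partial = K)[K])
  }
  w <- dnorm((scores - t) / h)
  sw <- sum(w)
  if (!is.finite(sw) || sw <= 0) return(NA_real_)
  min(max(sum(w * activity) / sw, 0), 1)
}

# Silverman-style rule-of-thumb bandwidth on the pooled score vector.
.rot_bandwidth <- function(scores) {
  1.06 * sd(scores) * length(scores)^(-1 / 5)
}

#' Threshold-specific activity rate via kernel regression
#'
#' Estimates \eqn{\Lambda_r = P(+ \mid S = t_r)}, the probability that a
#' ligand scoring exactly at the threshold is active, by Nadaraya-Watson
#' kernel regression of the activity labels on the pooled scores with a
#' Gaussian kernel. The default bandwidth is the rule-of-thumb
#' \eqn{h = 1.06\, \hat\sigma_S\, n^{-1/5}}, floored so that the kernel
#' window spans at least `min_neighbors` observations (spike protection in
#' the sparse extreme tail; set `min_neighbors = 0` for the pure
#' fixed-bandwidth estimate). The estimate is clipped to
#' `[0, 1]`. At the `r = 1` sentinel threshold (`-Inf`) the rate is
#' undefined and 0 is returned with `sentinel = TRUE`. If the kernel mass
#' at `t_hat` underflows, the overall active fraction is returned with
#' `fallback = TRUE` and a warning.
#'
#' @param data a [scored_dataset()].
#' @param method score column name.
#' @param t_hat threshold at which to evaluate the regression.
#' @param bandwidth optional kernel bandwidth (> 0) overriding the rule.
#' @param min_neighbors minimum number of observations the kernel window
#'   must span (default 20).
#' @return list of class `lambda_estimate`: `value`, `bandwidth`,
#'   `at_threshold`, `fallback`, `sentinel`.
#' @export
estimate_lambda <- function(data, method, t_hat, bandwidth = NULL,
                            min_neighbors = 20L) {
  s <- .method_scores(data, method)
  if (is.infinite(t_hat) && t_hat < 0) {
    return(structure(list(value = 0, bandwidth = NA_real_,
                          at_threshold = t_hat, fallback = FALSE,
                          sentinel = TRUE),
                     class = "lambda_estimate"))
  }
  if (!is.finite(t_hat)) stop("t_hat must be finite", call. = FALSE)
  h <- if (is.null(bandwidth)) .rot_bandwidth(s) else bandwidth
  if (!is.finite(h) || h <= 0) {
    # degenerate score spread: no local information, fall back to pi_hat
    warning("non-positive bandwidth; falling back to pi_hat")
    return(structure(list(value = data$pi_hat, bandwidth = h,
                          at_threshold = t_hat, fallback = TRUE,
                          sentinel = FALSE),
                     class = "lambda_estimate"))
  }
  v <- .nw_lambda(s, data$activity, t_hat, h, min_neighbors)
  fallback <- FALSE
  if (is.na(v)) {
    warning("zero kernel mass at threshold; falling back to pi_hat")
    v <- data$pi_hat
    fallback <- TRUE
  }
  structure(list(value = v, bandwidth = h, at_threshold = t_hat,
                 fallback = fallback, sentinel = FALSE),
            class = "lambda_estimate")
}

#' @export
print.lambda_estimate <- function(x, ...) {
  cat(sprintf("Lambda_hat = %.4g (bandwidth %.4g at t = %g)%s\n",
              x$value, x$bandwidth, x$at_threshold,
              if (x$fallback) " [fallback to pi_hat]" else ""))
  invisible(x)
}

# Wrap a raw (possibly negative) variance value: floor at 0 and record the
# diagnostic components.
.var_estimate <- function(raw, components = NULL) {
  floored <- is.finite(raw) && raw < 0
  structure(max(raw, 0), components = components, floored = floored,
            class = c("variance_estimate", "numeric"))
}

#' @export
print.variance_estimate <- function(x, ...) {
  cat(sprintf("variance estimate: %.6g%s\n", as.numeric(x),
              if (isTRUE(attr(x, "floored"))) " [floored at 0]" else ""))
  invisible(x)
}

#' Binomial variance of estimated recall
#'
#' \eqn{Var_B(\hat\theta_r) = \theta_r (1 - \theta_r) / (n\pi_+)}: the
#' variance recall would have if the tested count were a simple binomial
#' draw of the \eqn{n\pi_+} actives.
#'
#' @param theta recall in `[0, 1]`.
#' @param n_active number of active ligands, \eqn{n\pi_+ \ge 1}.
#' @return a `variance_estimate` (numeric scalar with attributes).
#' @export
var_binomial <- function(theta, n_active) {
  stopifnot(n_active >= 1, theta >= 0, theta <= 1)
  .var_estimate(theta * (1 - theta) / n_active)
}

#' Jiang-Zhao asymptotic variance of estimated recall
#'
#' The asymptotic variance of \eqn{\hat\theta_r} accounting for estimation
#' of the score threshold from the same data:
#' \deqn{Var_{JZ} = Var_B \left[1 - 2\Lambda_r +
#'   \frac{\Lambda_r^2 (1-r) r}{\pi_+ \theta_r (1-\theta_r)}\right].}
#' The bracket correction involves the threshold-specific activity rate
#' \eqn{\Lambda_r}; \eqn{\Lambda_r = 0} recovers the plain binomial
#' variance. For `theta` equal to 0 or 1 the variance degenerates to 0.
#' A negative raw value (possible with plug-in estimates) is floored at 0
#' and flagged.
#'
#' @param theta recall.
#' @param lambda threshold-specific activity rate \eqn{\Lambda_r}.
#' @param r testing fraction.
#' @param n library size.
#' @param pi activity rate \eqn{\pi_+}.
#' @return a `variance_estimate`.
#' @export
var_jz <- function(theta, lambda, r, n, pi) {
  stopifnot(theta >= 0, theta <= 1, pi > 0, pi < 1, r > 0, r <= 1)
  if (theta == 0 || theta == 1) {
    return(.var_estimate(0, components = c(var_b = 0, bracket = NA)))
  }
  var_b <- theta * (1 - theta) / (n * pi)
  bracket <- 1 - 2 * lambda +
    lambda^2 * (1 - r) * r / (pi * theta * (1 - theta))
  .var_estimate(var_b * bracket,
                components = c(var_b = var_b, bracket = bracket))
}

#' Covariance between binomial recall counts
#'
#' \eqn{Cov_B(\hat\theta_1, \hat\theta_2) =
#'   (\theta_{12} - \theta_1\theta_2) / (n\pi_+)}, where
#' \eqn{\theta_{12}} is the probability that an active ligand is tested by
#' both methods.
#'
#' @param theta1,theta2 marginal recalls.
#' @param theta12 joint recall; must satisfy the Frechet bounds
#'   `max(0, theta1 + theta2 - 1) <= theta12 <= min(theta1, theta2)`.
#' @param n_active number of actives \eqn{n\pi_+}.
#' @return numeric covariance (may be negative).
#' @export
cov_binomial <- function(theta1, theta2, theta12, n_active) {
  stopifnot(n_active >= 1)
  if (theta12 > min(theta1, theta2) + 1e-12 ||
      theta12 < max(0, theta1 + theta2 - 1) - 1e-12)
    stop("theta12 violates Frechet bounds", call. = FALSE)
  (theta12 - theta1 * theta2) / n_active
}

#' Empirical-process covariance between two methods at one fraction
#'
#' Covariance of \eqn{\hat\theta_{1r}} and \eqn{\hat\theta_{2r}} that
#' accounts both for the shared ligands and for threshold estimation,
#' evaluated in the expanded form
#' \deqn{(n\pi_+)^{-1}\left[(\theta_{12} - \theta_1\theta_2)
#'   (1 - \Lambda_1 - \Lambda_2) +
#'   (\gamma_{12} - r^2)\Lambda_1\Lambda_2/\pi_+\right]}
#' so that \eqn{\theta_{12} = \theta_1\theta_2} causes no 0/0.
#'
#' @param theta1,theta2 marginal recalls.
#' @param theta12 joint recall of the two methods.
#' @param gamma12 probability that a ligand (active or not) is tested by
#'   both methods.
#' @param lambda1,lambda2 threshold-specific activity rates.
#' @param r common testing fraction.
#' @param n library size.
#' @param pi activity rate.
#' @return numeric covariance (may be negative).
#' @export
cov_emproc <- function(theta1, theta2, theta12, gamma12,
                       lambda1, lambda2, r, n, pi) {
  stopifnot(pi > 0, pi < 1, r > 0, r <= 1)
  ((theta12 - theta1 * theta2) * (1 - lambda1 - lambda2) +
     (gamma12 - r^2) * lambda1 * lambda2 / pi) / (n * pi)
}

#' Empirical-process variance of a recall difference
#'
#' \eqn{Var(\hat\theta_{1r} - \hat\theta_{2r}) = Var_{JZ}(\hat\theta_{1r})
#'  + Var_{JZ}(\hat\theta_{2r}) - 2\,Cov_{EmProc}}; floored at 0.
#'
#' @param var1,var2 the two [var_jz()] values (numeric).
#' @param cov the [cov_emproc()] value.
#' @return a `variance_estimate`.
#' @export
var_emproc_diff <- function(var1, var2, cov) {
  .var_estimate(as.numeric(var1) + as.numeric(var2) - 2 * as.numeric(cov),
                components = c(var1 = as.numeric(var1),
                               var2 = as.numeric(var2),
                               cov = as.numeric(cov)))
}

#' Within-curve covariance of recall at two fractions
#'
#' Covariance of \eqn{\hat\theta_{r_i}} and \eqn{\hat\theta_{r_j}} for one
#' method at fractions \eqn{r_i < r_j}, in expanded form
#' \deqn{(n\pi_+)^{-1}\left[\theta_{r_i}(1-\theta_{r_j})
#'   (1-\Lambda_i-\Lambda_j) +
#'   r_i(1-r_j)\Lambda_i\Lambda_j/\pi_+\right].}
#' Equal fractions delegate to [var_jz()].
#'
#' @param theta_i,theta_j recalls at the smaller and larger fraction.
#' @param lambda_i,lambda_j threshold-specific activity rates.
#' @param r_i,r_j testing fractions with `r_i <= r_j`.
#' @param n library size.
#' @param pi activity rate.
#' @return numeric covariance.
#' @export
cov_within_curve <- function(theta_i, theta_j, lambda_i, lambda_j,
                             r_i, r_j, n, pi) {
  stopifnot(pi > 0, pi < 1, r_i > 0, r_j <= 1)
  if (r_i > r_j) stop("requires r_i <= r_j", call. = FALSE)
  if (r_i == r_j)
    return(as.numeric(var_jz(theta_i, lambda_i, r_i, n, pi)))
  (theta_i * (1 - theta_j) * (1 - lambda_i - lambda_j) +
     r_i * (1 - r_j) * lambda_i * lambda_j / pi) / (n * pi)
}

#' Cross-method cross-fraction covariance
#'
#' Covariance of \eqn{\hat\theta_{1r_i}} (method 1 at fraction
#' \eqn{r_i}) and \eqn{\hat\theta_{2r_j}} (method 2 at fraction
#' \eqn{r_j}), with no restriction between the fractions, in expanded form
#' \deqn{(n\pi_+)^{-1}\left[(\theta_{12\cdot ij} -
#'   \theta_{1i}\theta_{2j})(1-\Lambda_{1i}-\Lambda_{2j}) +
#'   (\gamma_{12\cdot ij} - r_i r_j)
#'   \Lambda_{1i}\Lambda_{2j}/\pi_+\right].}
#' Specialises to [cov_within_curve()] when the methods coincide and to
#' [cov_emproc()] when the fractions coincide.
#'
#' @param theta1_i recall of method 1 at `r_i`.
#' @param theta2_j recall of method 2 at `r_j`.
#' @param theta12_ij joint recall `P(tested by 1 at r_i and 2 at r_j | +)`.
#' @param gamma12_ij unconditional joint tested probability.
#' @param lambda1_i,lambda2_j threshold-specific activity rates.
#' @param r_i,r_j testing fractions.
#' @param n library size.
#' @param pi activity rate.
#' @return numeric covariance.
#' @export
cov_cross_alg_frac <- function(theta1_i, theta2_j, theta12_ij, gamma12_ij,
                               lambda1_i, lambda2_j, r_i, r_j, n, pi) {
  stopifnot(pi > 0, pi < 1, r_i > 0, r_j > 0, r_i <= 1, r_j <= 1)
  ((theta12_ij - theta1_i * theta2_j) * (1 - lambda1_i - lambda2_j) +
     (gamma12_ij - r_i * r_j) * lambda1_i * lambda2_j / pi) / (n * pi)
}
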