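#' Parametric score models
#'
#' Class-conditional score distributions for one ranking algorithm:
#' `binormal` (normal actives and inactives), `bibeta` (beta actives and
#' inactives), or `uniform`. These drive the synthetic-data generator and
#' the population-level oracles ([true_recall()] and friends).
#'
#' Parameter vectors are family specific: `c(mean, sd)` for binormal,
#' `c(shape1, shape2)` for bibeta, `c(min, max)` for uniform.
#'
#' @param family `"binormal"`, `"bibeta"`, or `"uniform"`.
#' @param active,inactive length-2 numeric parameter vectors for the
#'   active (+) and inactive (-) class.
#' @return object of class `score_model`.
#' @examples
#' score_model("binormal", active = c(0.8 * sqrt(2), 1),
#'             inactive = c(0, 1))
#' @export
score_model <- function(family = c("binormal", "bibeta", "uniform"),
                        active, inactive) {
  family <- match.arg(family)
  chk <- function(p, lab) {
    if (length(p) != 2L || anyNA(p) || !is.numeric(p))
      stop(sprintf("%s parameters must be a length-2 numeric vector", lab),
           call. = FALSE)
    ok <- switch(family,
                 binormal = p[2] > 0,
                 bibeta = all(p > 0),
                 uniform = p[1] < p[2])
    if (!ok) stop(sprintf("invalid %s parameters for %s model", lab, family),
                  call. = FALSE)
    as.numeric(p)
  }
  structure(list(family = family, active = chk(active, "active"),
                 inactive = chk(inactive, "inactive")),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("%s score model: active (%s), inactive (%s)\n", x$family,
              paste(signif(x$active, 4), collapse = ", "),
              paste(signif(x$inactive, 4), collapse = ", ")))
  invisible(x)
}

# Distribution-function dispatch for one class ("active"/"inactive").
.model_p <- function(model, side, q) {
  p <- model[[side]]
  switch(model$family,
         binormal = pnorm(q, p[1], p[2]),
         bibeta = pbeta(q, p[1], p[2]),
         uniform = punif(q, p[1], p[2]))
}
.model_d <- function(model, side, x) {
  p <- model[[side]]
  switch(model$family,
         binormal = dnorm(x, p[1], p[2]),
         bibeta = dbeta(x, p[1], p[2]),
         uniform = dunif(x, p[1], p[2]))
}
.model_q <- function(model, side, u) {
  p <- model[[side]]
  switch(model$family,
         binormal = qnorm(u, p[1], p[2]),
         bibeta = qbeta(u, p[1], p[2]),
         uniform = qunif(u, p[1], p[2]))
}

# Mixture cdf F_S = pi F_+ + (1 - pi) F_-.
.mixture_p <- function(model, pi_plus, q) {
  pi_plus * .model_p(model, "active", q) +
    (1 - pi_plus) * .model_p(model, "inactive", q)
}

#' Binormal two-algorithm benchmark model
#'
#' Both algorithms score inactives as N(0, 1); Algorithm 1 scores actives
#' as N(0.8\eqn{\sqrt 2}, 1) (Cohen's D = 0.8) and Algorithm 2 as
#' N(0.6\eqn{\sqrt 2}, 1) (Cohen's D = 0.6): two similar, strong scorers
#' on an extremely imbalanced library.
#'
#' @return list of two [score_model()]s.
#' @export
binormal_pair <- function() {
  list(alg1 = score_model("binormal", c(0.8 * sqrt(2), 1), c(0, 1)),
       alg2 = score_model("binormal", c(0.6 * sqrt(2), 1), c(0, 1)))
}

#' Bibeta two-algorithm benchmark model
#'
#' Both algorithms score inactives as Beta(2, 5); Algorithm 1 scores
#' actives as Beta(5, 2) and Algorithm 2 as Beta(4, 2). Separation is much
#' larger than in the binormal pair, giving high hit enrichment curves.
#'
#' @return list of two [score_model()]s.
#' @export
bibeta_pair <- function() {
  list(alg1 = score_model("bibeta", c(5, 2), c(2, 5)),
       alg2 = score_model("bibeta", c(4, 2), c(2, 5)))
}

#' Single-curve benchmark cases
#'
#' Five named single-algorithm score models spanning weak to very strong
#' class separation, used in the band-coverage studies:
#' 1. binormal, means 0 and 1.4, unit variances;
#' 2. binormal, means 0 and 0.5, unit variances;
#' 3. bibeta, Beta(2,5) inactive and Beta(5,2) active;
#' 4. bibeta, Beta(1,20) inactive and Beta(20,1) active;
#' 5. uniform(0, 0.75) inactive and uniform(0.25, 1) active.
#'
#' @param case integer 1..5.
#' @return a [score_model()].
#' @export
single_curve_case <- function(case) {
  stopifnot(length(case) == 1L, case %in% 1:5)
  switch(case,
         score_model("binormal", c(1.4, 1), c(0, 1)),
         score_model("binormal", c(0.5, 1), c(0, 1)),
         score_model("bibeta", c(5, 2), c(2, 5)),
         score_model("bibeta", c(20, 1), c(1, 20)),
         score_model("uniform", c(0.25, 1), c(0, 0.75)))
}

#' Cohen's D of a binormal score model
#'
#' \eqn{(\mu_+ - \mu_-)/\sqrt{\sigma_+^2 + \sigma_-^2}}.
#'
#' @param model a binormal [score_model()].
#' @return numeric effect size.
#' @export
cohens_d <- function(model) {
  stopifnot(inherits(model, "score_model"))
  if (model$family != "binormal")
    stop("Cohen's D is defined here for binormal models only",
         call. = FALSE)
  (model$active[1] - model$inactive[1]) /
    sqrt(model$active[2]^2 + model$inactive[2]^2)
}

#' Class skew
#'
#' Ratio of inactives to actives, \eqn{(1 - \pi_+)/\pi_+}; e.g. 499 for
#' \eqn{\pi_+ = 0.002}.
#'
#' @param pi_plus activity rate in (0, 1).
#' @return numeric skew.
#' @export
class_skew <- function(pi_plus) {
  stopifnot(pi_plus > 0, pi_plus < 1)
  (1 - pi_plus) / pi_plus
}

#' Population score threshold at a testing fraction
#'
#' Solves \eqn{F_S(t_r) = 1 - r} for the mixture cdf
#' \eqn{F_S = \pi_+ F_+ + (1-\pi_+)F_-} by monotone root finding
#' (tolerance 1e-10). `r = 1` returns `-Inf`.
#'
#' @param model a [score_model()].
#' @param pi_plus activity rate.
#' @param r testing fraction(s) in (0, 1].
#' @return numeric threshold(s).
#' @export
true_threshold <- function(model, pi_plus, r) {
  stopifnot(inherits(model, "score_model"), pi_plus > 0, pi_plus < 1,
            all(r > 0), all(r <= 1))
  lo <- min(.model_q(model, "active", 1e-14),
            .model_q(model, "inactive", 1e-14))
  hi <- max(.model_q(model, "active", 1 - 1e-14),
            .model_q(model, "inactive", 1 - 1e-14))
  vapply(r, function(ri) {
    if (ri == 1) return(-Inf)
    uniroot(function(t) .mixture_p(model, pi_plus, t) - (1 - ri),
            lower = lo, upper = hi, extendInt = "upX",
            tol = 1e-10)$root
  }, numeric(1))
}

#' Population recall at a testing fraction
#'
#' \eqn{\theta_r = 1 - F_+(t_r)} where \eqn{t_r} solves
#' \eqn{F_S(t_r) = 1 - r}. A useless scorer (identical class
#' distributions) has \eqn{\theta_r = r}.
#'
#' @inheritParams true_threshold
#' @return numeric recall value(s).
#' @export
true_recall <- function(model, pi_plus, r) {
  t <- true_threshold(model, pi_plus, r)
  1 - .model_p(model, "active", t)
}

#' Population threshold-specific activity rate
#'
#' \eqn{\Lambda_r = P(+ \mid S = t_r) = \pi_+ f_+(t_r) /
#'   [\pi_+ f_+(t_r) + (1-\pi_+) f_-(t_r)]}.
#'
#' @inheritParams true_threshold
#' @return numeric rate(s) in `[0, 1]`.
#' @export
true_lambda <- function(model, pi_plus, r) {
  t <- true_threshold(model, pi_plus, r)
  fp <- pi_plus * .model_d(model, "active", t)
  fm <- (1 - pi_plus) * .model_d(model, "inactive", t)
  ifelse(fp + fm > 0, fp / (fp + fm), 0)
}

# Upper-quadrant probability P(Z1 > a, Z2 > b) for standard bivariate
# normal with correlation rho, by 1-D Gaussian quadrature. mvtnorm is not
# a dependency; this is accurate to ~1e-10 and handles infinite limits.
.bvn_upper <- function(a, b, rho) {
  if (a == Inf || b == Inf) return(0)
  if (a == -Inf) return(pnorm(b, lower.tail = FALSE))
  if (b == -Inf) return(pnorm(a, lower.tail = FALSE))
  if (rho >= 1) return(pnorm(max(a, b), lower.tail = FALSE))
  if (rho <= -1) return(max(0, pnorm(-b) - pnorm(a)))
  sr <- sqrt(1 - rho^2)
  integrate(function(z) dnorm(z) *
              pnorm((b - rho * z) / sr, lower.tail = FALSE),
            lower = a, upper = Inf, rel.tol = 1e-10,
            abs.tol = 1e-13)$value
}

#' Population joint tested probabilities for two correlated algorithms
#'
#' For two score models sharing a Gaussian copula with parameter `rho`
#' within each class, computes \eqn{\theta_{12 \cdot r_i r_j} =
#' P(S_1 > t_{1 r_i}, S_2 > t_{2 r_j} \mid +)} and the unconditional
#' analogue \eqn{\gamma_{12 \cdot r_i r_j}}, at possibly different
#' testing fractions.
#'
#' @param model1,model2 [score_model()]s for the two algorithms.
#' @param pi_plus activity rate.
#' @param rho Gaussian copula parameter in `(-1, 1)` (or degenerate
#'   \eqn{\pm 1}).
#' @param r1 testing fraction for algorithm 1.
#' @param r2 testing fraction for algorithm 2; defaults to `r1`.
#' @return list with `theta12`, `gamma12`, `t1`, `t2`.
#' @export
true_paired_prob <- function(model1, model2, pi_plus, rho, r1, r2 = r1) {
  t1 <- true_threshold(model1, pi_plus, r1)
  t2 <- true_threshold(model2, pi_plus, r2)
  quad <- function(side) {
    u1 <- .model_p(model1, side, t1)
    u2 <- .model_p(model2, side, t2)
    .bvn_upper(qnorm(u1), qnorm(u2), rho)
  }
  th12 <- quad("active")
  g12 <- pi_plus * th12 + (1 - pi_plus) * quad("inactive")
  list(theta12 = th12, gamma12 = g12, t1 = t1, t2 = t2)
}
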