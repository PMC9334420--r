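#' Simulate a scored benchmark dataset
#'
#' Draws activity labels and one or two correlated score columns from
#' parametric class-conditional models. Labels are Bernoulli(\eqn{\pi_+})
#' by default (or a fixed count `round(n * pi_plus)` in random order).
#' With two models, scores within each class share a Gaussian copula with
#' parameter `rho` while keeping the specified marginals; the two classes
#' are sampled independently. For binormal marginals this is exactly a
#' bivariate normal with correlation `rho`.
#'
#' The defaults emulate a MUV-style virtual-screening benchmark: a large
#' library with extreme class imbalance
#' (`n = 150000`, `pi_plus = 0.002`, skew 499).
#'
#' @param n library size.
#' @param pi_plus activity rate in (0, 1).
#' @param models a [score_model()] or list of one or two of them.
#' @param rho Gaussian-copula correlation between the two score columns
#'   within each class (ignored for a single model).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @param activity_sampling `"bernoulli"` or `"fixed"` (exact count).
#' @return a [scored_dataset()] with columns named after `models` (or
#'   `alg1`, `alg2`).
#' @examples
#' d <- simulate_scores(1000, 0.05, binormal_pair(), rho = 0.9, seed = 1)
#' d
#' @export
simulate_scores <- function(n = 150000, pi_plus = 0.002, models,
                            rho = 0, seed = NULL,
                            activity_sampling = c("bernoulli", "fixed")) {
  activity_sampling <- match.arg(activity_sampling)
  if (inherits(models, "score_model")) models <- list(models)
  stopifnot(length(models) %in% 1:2, n >= 2, pi_plus > 0, pi_plus < 1,
            rho > -1, rho < 1)
  for (m in models) stopifnot(inherits(m, "score_model"))
  nm <- names(models)
  if (is.null(nm) || any(nm == ""))
    nm <- paste0("alg", seq_along(models))
  with_seed(seed, {
    act <- if (activity_sampling == "bernoulli") {
      rbinom(n, 1L, pi_plus)
    } else {
      k <- max(1L, round(n * pi_plus))
      sample(c(rep(1L, k), rep(0L, n - k)))
    }
    k <- length(models)
    z <- matrix(rnorm(n * k), n, k)
    if (k == 2L && rho != 0) {
      z <- z %*% chol(matrix(c(1, rho, rho, 1), 2))
    }
    scores <- matrix(0, n, k, dimnames = list(NULL, nm))
    idx_a <- act == 1L
    for (j in seq_len(k)) {
      mj <- models[[j]]
      for (side in c("active", "inactive")) {
        idx <- if (side == "active") idx_a else !idx_a
        if (!any(idx)) next
        scores[idx, j] <- if (mj$family == "binormal") {
          # exact: normal marginal of the Gaussian copula
          mj[[side]][1] + mj[[side]][2] * z[idx, j]
        } else {
          .model_q(mj, side, pnorm(z[idx, j]))
        }
      }
    }
    scored_dataset(act, scores)
  })
}

# Paired per-count statistics for one simulated replicate: for each tested
# count c, thresholds for both methods, Q1/Q2/Q12, and gamma_hat.
.pair_stats <- function(s1, s2, activity, counts) {
  n <- length(s1)
  o1 <- sort(s1)
  o2 <- sort(s2)
  act <- activity == 1L
  k <- length(counts)
  out <- matrix(0, k, 6,
                dimnames = list(NULL,
                                c("t1", "t2", "Q1", "Q2", "Q12", "gamma")))
  for (i in seq_len(k)) {
    j <- n - counts[i]
    t1 <- if (j < 1) -Inf else o1[j]
    t2 <- if (j < 1) -Inf else o2[j]
    T1 <- s1 > t1
    T2 <- s2 > t2
    out[i, ] <- c(t1, t2, sum(T1 & act), sum(T2 & act),
                  sum(T1 & T2 & act), mean(T1 & T2))
  }
  out
}

# |Z| statistics for every (count, procedure) cell of one replicate.
.compare_fast <- function(s1, s2, activity, counts, procedures,
                          pooled = FALSE, plus = FALSE) {
  n <- length(s1)
  m <- sum(activity)
  st <- .pair_stats(s1, s2, activity, counts)
  h1 <- .rot_bandwidth(s1)
  h2 <- .rot_bandwidth(s2)
  need_lambda <- any(procedures %in% c("EmProc", "IndJZ"))
  zmat <- matrix(NA_real_, length(counts), length(procedures),
                 dimnames = list(counts, procedures))
  for (i in seq_along(counts)) {
    r <- counts[i] / n
    l1 <- l2 <- NULL
    if (need_lambda) {
      l1 <- .nw_lambda(s1, activity, st[i, "t1"], h1)
      l2 <- .nw_lambda(s2, activity, st[i, "t2"], h2)
      if (is.na(l1)) l1 <- m / n
      if (is.na(l2)) l2 <- m / n
    }
    for (p in procedures) {
      inf <- .diff_inference(st[i, "Q1"], st[i, "Q2"], st[i, "Q12"],
                             st[i, "gamma"], m, n, r, l1, l2,
                             p, pooled, plus)
      if (is.finite(inf$se) && inf$se > 0)
        zmat[i, p] <- abs(inf$center / inf$se)
    }
  }
  zmat
}

#' Monte-Carlo power / type-I error study
#'
#' Repeatedly simulates a two-algorithm benchmark and records, for each
#' tested count and procedure, the fraction of replicates where
#' \eqn{|Z_r| > z_{\alpha/2}}. With identical models this estimates the
#' type-I error rate; with different models, power.
#'
#' @param models list of two [score_model()]s.
#' @param n library size per replicate.
#' @param pi_plus activity rate.
#' @param rho within-class Gaussian-copula correlation of the two scores.
#' @param counts integer vector of tested counts (the grid).
#' @param replicates number of Monte-Carlo replicates.
#' @param procedures subset of `c("EmProc", "IndJZ", "CorrBinom",
#'   "McNemar")`.
#' @param alpha test level.
#' @param pooled,plus variance options passed to the tests.
#' @param seed optional integer seed.
#' @return data frame of class `study_result` with columns `count`, `r`,
#'   `procedure`, `rate`, `mc_se`, `replicates`. A replicate with a
#'   degenerate (zero-SE) statistic counts as a non-rejection.
#' @export
run_power_study <- function(models, n = 20000, pi_plus = 0.01, rho = 0.9,
                            counts = c(2, 8, 32, 128, 512, 2000),
                            replicates = 1000,
                            procedures = c("EmProc", "IndJZ", "CorrBinom",
                                           "McNemar"),
                            alpha = 0.05, pooled = FALSE, plus = FALSE,
                            seed = NULL) {
  stopifnot(length(models) == 2L, replicates >= 1)
  counts <- sort(unique(as.integer(counts)))
  zq <- qnorm(1 - alpha / 2)
  rej <- matrix(0, length(counts), length(procedures),
                dimnames = list(counts, procedures))
  with_seed(seed, {
    for (b in seq_len(replicates)) {
      d <- simulate_scores(n, pi_plus, models, rho)
      if (d$n_active < 1L || d$n_active > d$n - 1L) next
      zmat <- .compare_fast(d$scores[, 1], d$scores[, 2], d$activity,
                            counts, procedures, pooled, plus)
      rej <- rej + (!is.na(zmat) & zmat > zq)
    }
  })
  rate <- rej / replicates
  out <- data.frame(
    count = rep(counts, times = length(procedures)),
    r = rep(counts / n, times = length(procedures)),
    procedure = rep(procedures, each = length(counts)),
    rate = as.vector(rate),
    mc_se = as.vector(sqrt(rate * (1 - rate) / replicates)),
    replicates = replicates, stringsAsFactors = FALSE)
  attr(out, "config") <- list(n = n, pi_plus = pi_plus, rho = rho,
                              skew = class_skew(pi_plus), alpha = alpha,
                              pooled = pooled, plus = plus, seed = seed)
  class(out) <- c("study_result", "data.frame")
  out
}

#' Monte-Carlo coverage study for confidence bands
#'
#' Simulates repeatedly and records how often a simultaneous band contains
#' the entire true curve (single algorithm) or true difference curve (two
#' algorithms), together with the average band width. True curves come
#' from [true_recall()].
#'
#' @param models a single [score_model()] (single-curve bands) or a list
#'   of two (difference bands).
#' @param n,pi_plus,rho,counts,replicates,seed as in [run_power_study()].
#' @param band_types subset of `c("sup-t", "bonferroni",
#'   "theta-projection")`.
#' @param plus_options logical vector of plus-adjustment settings to
#'   cross with `band_types`.
#' @param alpha band level.
#' @param draws Monte-Carlo draws for each sup-t critical value.
#' @return data frame of class `study_result` with columns `band_type`,
#'   `plus`, `coverage`, `mc_se`, `avg_width`, `replicates`.
#' @export
run_coverage_study <- function(models, n = 20000, pi_plus = 0.01,
                               rho = 0.9, counts = 2^(1:10),
                               replicates = 500,
                               band_types = c("sup-t", "bonferroni"),
                               plus_options = c(TRUE, FALSE),
                               alpha = 0.05, draws = 20000, seed = NULL) {
  single <- inherits(models, "score_model")
  if (!single) stopifnot(length(models) == 2L)
  counts <- sort(unique(as.integer(counts)))
  fr <- counts / n
  truth <- if (single) {
    true_recall(models, pi_plus, fr)
  } else {
    true_recall(models[[1]], pi_plus, fr) -
      true_recall(models[[2]], pi_plus, fr)
  }
  configs <- expand.grid(band_type = band_types, plus = plus_options,
                         stringsAsFactors = FALSE)
  hits <- numeric(nrow(configs))
  widths <- numeric(nrow(configs))
  used <- 0L
  with_seed(seed, {
    for (b in seq_len(replicates)) {
      d <- simulate_scores(n, pi_plus, models, rho)
      if (d$n_active < 1L || d$n_active > d$n - 1L) next
      used <- used + 1L
      for (plus in unique(configs$plus)) {
        cc <- if (single) {
          .single_cov(d, 1L, fr, plus = plus)
        } else {
          .diff_cov(d, 1L, 2L, fr, plus = plus)
        }
        se <- sqrt(pmax(diag(cc$V), 0))
        for (bt in band_types) {
          q <- switch(bt,
                      "sup-t" = supt_critical(cc$V, alpha, draws),
                      "bonferroni" = bonferroni_critical(length(fr), alpha),
                      "theta-projection" =
                        theta_projection_critical(length(fr), alpha))
          ci <- which(configs$band_type == bt & configs$plus == plus)
          covered <- all(abs(cc$theta - truth) <= q * se)
          hits[ci] <- hits[ci] + covered
          widths[ci] <- widths[ci] + mean(2 * q * se)
        }
      }
    }
  })
  cov_rate <- hits / used
  out <- data.frame(
    band_type = configs$band_type, plus = configs$plus,
    coverage = cov_rate,
    mc_se = sqrt(cov_rate * (1 - cov_rate) / used),
    avg_width = widths / used,
    replicates = used, stringsAsFactors = FALSE)
  attr(out, "config") <- list(n = n, pi_plus = pi_plus, rho = rho,
                              skew = class_skew(pi_plus), counts = counts,
                              alpha = alpha, draws = draws, seed = seed)
  class(out) <- c("study_result", "data.frame")
  out
}
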