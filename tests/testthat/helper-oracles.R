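# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the order-statistic shortcuts used by the package:
# thresholds are found by scanning the empirical cdf over every observed
# score value, counts by explicit enumeration over ligands.

oracle_threshold <- function(scores, r) {
  if (r == 1) return(-Inf)
  cand <- sort(unique(scores))
  for (t in cand) {
    # tolerance: 1 - r is not exactly representable for r = k/n
    if (mean(scores <= t) >= 1 - r - 1e-9) return(t)
  }
  stop("no threshold found")
}

oracle_counts <- function(activity, s1, s2, r1, r2) {
  t1 <- oracle_threshold(s1, r1)
  t2 <- oracle_threshold(s2, r2)
  q1 <- q2 <- q12 <- g <- 0
  for (i in seq_along(activity)) {
    in1 <- s1[i] > t1
    in2 <- s2[i] > t2
    if (in1 && in2) g <- g + 1
    if (activity[i] == 1) {
      if (in1) q1 <- q1 + 1
      if (in2) q2 <- q2 + 1
      if (in1 && in2) q12 <- q12 + 1
    }
  }
  list(Q1 = q1, Q2 = q2, Q12 = q12, gamma = g / length(activity))
}

# random dataset with heavy ties (scores rounded to a coarse lattice)
random_tied_dataset <- function(n, n_methods = 2, p_active = 0.4) {
  act <- rbinom(n, 1, p_active)
  if (sum(act) == 0) act[sample(n, 1)] <- 1L
  if (sum(act) == n) act[sample(n, 1)] <- 0L
  sc <- matrix(round(rnorm(n * n_methods), 1), n, n_methods)
  colnames(sc) <- paste0("m", seq_len(n_methods))
  scored_dataset(act, sc)
}

# paired_tested_counts object from raw cell counts (for interval formulas)
make_counts <- function(Q1, Q2, Q12, n_active, r = 0.1, n = NULL) {
  if (is.null(n)) n <- n_active * 10
  structure(list(Q1 = Q1, Q2 = Q2, Q12 = Q12, n_active = n_active,
                 gamma_hat = Q12 / n, r1 = r, r2 = r, t1 = 0, t2 = 0,
                 n = n, pi_hat = n_active / n,
                 method1 = "a", method2 = "b"),
            class = "paired_tested_counts")
}
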