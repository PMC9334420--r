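test_that("tie-safe thresholds follow the inverse-cdf definition", {
  expect_equal(threshold_at_fraction(1:5, 0.2), 4)
  expect_equal(threshold_at_fraction(rep(1, 4), 0.5), 1)
  expect_equal(threshold_at_fraction(c(3, 1, 2), 1), -Inf)
  # ligands tied at the threshold are not tested
  expect_equal(sum(rep(1, 4) > threshold_at_fraction(rep(1, 4), 0.5)), 0)
  expect_error(threshold_at_fraction(1:5, 0), "invalid fraction")
  expect_error(threshold_at_fraction(1:5, -0.1), "invalid fraction")
  expect_error(threshold_at_fraction(1:5, 0.1), "invalid fraction")
  expect_error(threshold_at_fraction(numeric(0), 0.5), "nonempty")
})

test_that("recall matches hand enumeration and ideal/worst cases", {
  d <- scored_dataset(c(1, 0, 1, 0), c(4, 3, 2, 1))
  rp <- recall_at_fraction(d, "alg1", 0.5)
  expect_equal(rp$t_hat, 2)
  expect_equal(rp$Q, 1L)
  expect_equal(rp$theta_hat, 0.5)
  # actives hold the top scores: recall 1 at r = n_active/n
  act <- c(rep(1, 3), rep(0, 7))
  ideal <- scored_dataset(act, 10:1)
  expect_equal(recall_at_fraction(ideal, "alg1", 0.3)$theta_hat, 1)
  worst <- scored_dataset(rev(act), 10:1)
  expect_equal(recall_at_fraction(worst, "alg1", 0.7)$theta_hat, 0)
  expect_error(recall_at_fraction(d, "nope", 0.5), "unknown method")
})

test_that("hit enrichment curves are monotone and end at recall 1", {
  set.seed(41)
  for (i in 1:25) {
    d <- random_tied_dataset(sample(10:120, 1))
    fr <- testing_fraction_grid(d$n, counts = unique(sample(d$n, 6)))
    hec <- hit_enrichment_curve(d, "m1", fr)
    expect_true(all(diff(hec$theta_hat) >= 0))
    # tested-fraction contract: never test more than r * n ligands
    expect_true(all(hec$n_tested <= hec$r * d$n + 1e-9))
    expect_equal(hit_enrichment_curve(d, "m1", 1)$theta_hat, 1)
  }
})

test_that("single-point grids agree with recall_at_fraction", {
  set.seed(7)
  d <- random_tied_dataset(60)
  hec <- hit_enrichment_curve(d, "m2", 0.25)
  rp <- recall_at_fraction(d, "m2", 0.25)
  expect_equal(hec$theta_hat, rp$theta_hat)
  expect_equal(hec$t_hat, rp$t_hat)
})

test_that("counts match exhaustive enumeration on tiny datasets", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    d <- random_tied_dataset(n)
    r1 <- sample(seq_len(n), 1) / n
    r2 <- sample(seq_len(n), 1) / n
    pc <- paired_tested_counts(d, "m1", "m2", r1, r2)
    oc <- oracle_counts(d$activity, d$scores[, 1], d$scores[, 2], r1, r2)
    expect_equal(pc$Q1, oc$Q1)
    expect_equal(pc$Q2, oc$Q2)
    expect_equal(pc$Q12, oc$Q12)
    expect_equal(pc$gamma_hat, oc$gamma)
    expect_equal(pc$t1, oracle_threshold(d$scores[, 1], r1))
  }
})

test_that("paired counts handle identity, reversal, and vacuous cases", {
  d <- scored_dataset(c(1, 1, 0, 0), cbind(a = c(4, 3, 2, 1),
                                           b = c(1, 2, 3, 4)))
  pc <- paired_tested_counts(d, "a", "b", 0.5)
  expect_equal(c(pc$Q1, pc$Q2, pc$Q12), c(2L, 0L, 0L))
  expect_equal(pc$gamma_hat, 0)
  same <- paired_tested_counts(d, "a", "a", 0.5)
  expect_equal(same$Q1, same$Q12)
  expect_equal(same$Q2, same$Q12)
  # r2 = 1 makes the second test vacuous
  vac <- paired_tested_counts(d, "a", "b", 0.5, 1)
  expect_equal(vac$Q12, vac$Q1)
  expect_equal(vac$gamma_hat, 0.5)
})

test_that("enrichment factor curve rescales recall by the fraction", {
  d <- scored_dataset(c(rep(1, 2), rep(0, 8)), 10:1)
  efc <- enrichment_factor_curve(d, "alg1", c(0.2, 1))
  expect_equal(efc$ef[efc$r == 1], 1)
  # ideal scorer at r = n_active/n has EF = n / n_active
  expect_equal(enrichment_factor_curve(d, "alg1", 0.2)$ef, 5)
})

test_that("random scores give a near-diagonal curve", {
  set.seed(5)
  d <- scored_dataset(rbinom(20000, 1, 0.1), runif(20000))
  fr <- c(0.05, 0.2, 0.5)
  hec <- hit_enrichment_curve(d, "alg1", fr)
  tol <- 3 * sqrt(fr * (1 - fr) / d$n_active)
  expect_true(all(abs(hec$theta_hat - fr) < tol))
})

test_that("fraction grids validate and convert counts", {
  g <- testing_fraction_grid(1000, counts = c(10, 2, 10, 100))
  expect_equal(g$fractions, c(2, 10, 100) / 1000)
  expect_error(testing_fraction_grid(1000, counts = 0.5), "\\[1, n\\]")
  expect_error(testing_fraction_grid(1000, fractions = c(0.1, 1.2)),
               "\\(0, 1\\]")
  expect_error(testing_fraction_grid(1000, fractions = 5e-4),
               "at least one")
  expect_error(testing_fraction_grid(1000), "exactly one")
  expect_error(hit_enrichment_curve(
    scored_dataset(c(1, 0), c(1, 2)), "alg1", numeric(0)), "grid")
  # default band grid has 25 points for large libraries
  expect_length(default_count_grid(150000)$fractions, 25)
  expect_lte(max(default_count_grid(5000)$fractions), 1)
})
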