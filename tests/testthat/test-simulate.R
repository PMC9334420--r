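test_that("score models validate their parameters", {
  expect_error(score_model("binormal", c(0, -1), c(0, 1)), "invalid")
  expect_error(score_model("bibeta", c(0, 2), c(2, 5)), "invalid")
  expect_error(score_model("uniform", c(1, 0), c(0, 1)), "invalid")
  expect_equal(cohens_d(binormal_pair()$alg1), 0.8)
  expect_equal(cohens_d(binormal_pair()$alg2), 0.6)
  expect_equal(class_skew(0.002), 499)
})

test_that("simulated datasets honour seed, rate, and copula correlation", {
  mods <- binormal_pair()
  d1 <- simulate_scores(20000, 0.01, mods, rho = 0.9, seed = 5)
  d2 <- simulate_scores(20000, 0.01, mods, rho = 0.9, seed = 5)
  expect_identical(d1$scores, d2$scores)
  expect_identical(d1$activity, d2$activity)
  expect_lt(abs(d1$pi_hat - 0.01), 3 * sqrt(0.01 * 0.99 / 20000))
  for (cls in c(TRUE, FALSE)) {
    idx <- (d1$activity == 1) == cls
    expect_lt(abs(cor(d1$scores[idx, 1], d1$scores[idx, 2]) - 0.9), 0.02)
  }
  d0 <- simulate_scores(20000, 0.01, mods, rho = 0, seed = 6)
  idx <- d0$activity == 0
  expect_lt(abs(cor(d0$scores[idx, 1], d0$scores[idx, 2])), 0.03)
  # fixed-count sampling gives exactly round(n * pi) actives
  df <- simulate_scores(1000, 0.05, mods, seed = 7,
                        activity_sampling = "fixed")
  expect_equal(df$n_active, 50L)
  # bibeta marginals stay inside (0, 1)
  db <- simulate_scores(5000, 0.05, bibeta_pair(), rho = 0.9, seed = 8)
  expect_true(all(db$scores > 0 & db$scores < 1))
})

test_that("population recall oracles behave at the limits", {
  m <- single_curve_case(1)
  expect_equal(true_recall(m, 0.01, 1), 1)
  expect_lt(true_recall(m, 0.01, 1e-5), 0.01)
  # useless scorer: recall equals the testing fraction
  useless <- score_model("binormal", c(0, 1), c(0, 1))
  rs <- c(0.01, 0.3, 0.8)
  expect_equal(true_recall(useless, 0.05, rs), rs, tolerance = 1e-8)
  # recall is monotone in r and the threshold decreases
  rr <- true_recall(m, 0.01, c(0.001, 0.01, 0.1, 0.5))
  expect_true(all(diff(rr) > 0))
  tt <- true_threshold(m, 0.01, c(0.001, 0.01, 0.1, 0.5))
  expect_true(all(diff(tt) < 0))
  # the mixture cdf is recovered: F_S(t_r) = 1 - r
  t <- true_threshold(m, 0.01, 0.07)
  expect_equal(0.01 * pnorm(t, 1.4, 1) + 0.99 * pnorm(t), 0.93,
               tolerance = 1e-8)
})

test_that("population recall matches large-sample empirical recall", {
  m <- single_curve_case(3)
  set.seed(51)
  d <- simulate_scores(200000, 0.01, m)
  r <- 0.01
  emp <- recall_at_fraction(d, "alg1", r)$theta_hat
  tol <- 4 * sqrt(0.25 / d$n_active)
  expect_lt(abs(emp - true_recall(m, 0.01, r)), tol)
})

test_that("joint tested probabilities match Monte Carlo", {
  mods <- binormal_pair()
  tp <- true_paired_prob(mods[[1]], mods[[2]], 0.01, 0.9, 0.05, 0.02)
  set.seed(53)
  d <- simulate_scores(400000, 0.01, mods, rho = 0.9)
  a <- d$activity == 1
  emp12 <- mean(d$scores[a, 1] > tp$t1 & d$scores[a, 2] > tp$t2)
  empg <- mean(d$scores[, 1] > tp$t1 & d$scores[, 2] > tp$t2)
  expect_lt(abs(emp12 - tp$theta12),
            3 * sqrt(tp$theta12 * (1 - tp$theta12) / sum(a)))
  expect_lt(abs(empg - tp$gamma12),
            3 * sqrt(tp$gamma12 * (1 - tp$gamma12) / d$n))
  # zero copula correlation factorises
  tp0 <- true_paired_prob(mods[[1]], mods[[2]], 0.01, 0, 0.05, 0.05)
  th1 <- true_recall(mods[[1]], 0.01, 0.05)
  th2 <- true_recall(mods[[2]], 0.01, 0.05)
  expect_equal(tp0$theta12, th1 * th2, tolerance = 1e-8)
})

test_that("study harness bookkeeping", {
  mods <- binormal_pair()
  st <- run_power_study(mods, n = 2000, pi_plus = 0.05, rho = 0.5,
                        counts = c(10, 100), replicates = 1,
                        procedures = "McNemar", seed = 3)
  expect_true(all(st$rate %in% c(0, 1)))
  expect_equal(attr(st, "config")$skew, class_skew(0.05))
  st2 <- run_power_study(mods, n = 2000, pi_plus = 0.05, rho = 0.5,
                         counts = c(10, 100), replicates = 20,
                         procedures = c("EmProc", "McNemar"), seed = 3)
  expect_equal(st2$mc_se, sqrt(st2$rate * (1 - st2$rate) / 20))
  cov <- run_coverage_study(single_curve_case(1), n = 2000,
                            pi_plus = 0.05, counts = c(20, 200),
                            replicates = 20, band_types = "bonferroni",
                            plus_options = TRUE, seed = 4)
  expect_true(all(cov$coverage >= 0 & cov$coverage <= 1))
  expect_true(all(cov$avg_width > 0))
})
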