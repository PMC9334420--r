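test_that("analytic critical multipliers", {
  expect_equal(bonferroni_critical(1), qnorm(0.975))
  expect_equal(bonferroni_critical(2), sqrt(qchisq(1 - 0.025, 1)))
  expect_equal(theta_projection_critical(1), qnorm(0.975))
  expect_equal(theta_projection_critical(2), sqrt(qchisq(0.95, 2)),
               tolerance = 1e-10)
  ks <- 1:50
  bq <- vapply(ks, bonferroni_critical, numeric(1))
  expect_true(all(diff(bq) > 0))
  # theta-projection bands are at least as wide as Bonferroni
  pq <- vapply(ks, theta_projection_critical, numeric(1))
  expect_true(all(pq >= bq - 1e-12))
})

test_that("sup-t critical value matches closed forms", {
  expect_equal(as.numeric(supt_critical(diag(1), draws = 2e5, seed = 1)),
               qnorm(0.975), tolerance = 0.02)
  # perfectly correlated components behave like a single comparison
  expect_equal(as.numeric(supt_critical(matrix(1, 3, 3), draws = 2e5,
                                        seed = 1)),
               qnorm(0.975), tolerance = 0.02)
  # two independent components: product of marginals
  q2 <- supt_critical(diag(2), draws = 4e5, seed = 2)
  expect_equal(as.numeric(q2), qnorm((1 + sqrt(0.95)) / 2),
               tolerance = 0.02)
  expect_lt(as.numeric(q2), bonferroni_critical(2))
  # reproducible under a fixed seed, error for all-zero covariance
  expect_identical(supt_critical(diag(3), draws = 1e4, seed = 9),
                   supt_critical(diag(3), draws = 1e4, seed = 9))
  expect_error(supt_critical(matrix(0, 2, 2)), "zero variance")
  expect_error(supt_critical(diag(2), draws = 100), "10\\^4")
})

test_that("critical values order as sup-t <= Bonferroni <= theta-projection", {
  set.seed(33)
  for (i in 1:12) {
    k <- sample(2:8, 1)
    A <- matrix(rnorm(k * k), k)
    V <- crossprod(A) + diag(k) * 0.1
    qs <- as.numeric(supt_critical(V, draws = 5e4))
    qb <- bonferroni_critical(k)
    qp <- theta_projection_critical(k)
    expect_lte(qs, qb + 0.05)  # MC slack on the sup-t estimate
    expect_lte(qb, qp + 1e-12)
  }
})

test_that("single-curve covariance matches its building blocks", {
  set.seed(37)
  d <- simulate_scores(5000, 0.05, single_curve_case(1))
  fr <- c(0.01, 0.05, 0.2)
  cc <- curve_covariance(d, "alg1", fr)
  expect_equal(dim(cc$V), c(3L, 3L))
  expect_equal(cc$V, t(cc$V))
  expect_true(all(eigen(cc$V, symmetric = TRUE)$values >= -1e-12))
  # diagonal is the Jiang-Zhao variance at the same plug-ins
  for (i in 1:3) {
    expect_equal(cc$V[i, i],
                 as.numeric(var_jz(cc$theta_var[i], cc$lambda[i],
                                   cc$r_eff[i], cc$n_eff,
                                   cc$m_eff / cc$n_eff)))
  }
  expect_equal(cc$V[1, 2],
               cov_within_curve(cc$theta_var[1], cc$theta_var[2],
                                cc$lambda[1], cc$lambda[2],
                                cc$r_eff[1], cc$r_eff[2],
                                cc$n_eff, cc$m_eff / cc$n_eff))
  # k = 1 reduces to a 1x1 Jiang-Zhao variance
  c1 <- curve_covariance(d, "alg1", 0.05)
  expect_equal(dim(c1$V), c(1L, 1L))
  expect_equal(c1$V[1, 1],
               as.numeric(var_jz(c1$theta_var, c1$lambda, c1$r_eff,
                                 c1$n_eff, c1$m_eff / c1$n_eff)))
})

test_that("difference covariance cancels for identical methods", {
  set.seed(43)
  d <- simulate_scores(4000, 0.05, single_curve_case(1))
  d <- add_score(d, "copy", d$scores[, "alg1"])
  cc <- curve_covariance_diff(d, "alg1", "copy", c(0.01, 0.1))
  expect_true(all(abs(cc$V) < 1e-12))
  expect_true(all(cc$theta_hat == 0))
  b <- confidence_band_diff(d, "alg1", "copy", c(0.01, 0.1),
                            plus = FALSE)
  expect_true(b$degenerate)
  expect_equal(b$table$lower, b$table$upper)
})

test_that("bands nest their center, clip, and reproduce under a seed", {
  set.seed(47)
  d <- simulate_scores(20000, 0.01, binormal_pair(), rho = 0.5)
  grid <- testing_fraction_grid(d$n, counts = c(4, 32, 256, 2000))
  b <- confidence_band(d, "alg1", grid, plus = TRUE, draws = 2e4,
                       seed = 3)
  expect_true(all(b$table$lower <= b$table$center + 1e-12))
  expect_true(all(b$table$center <= b$table$upper + 1e-12))
  expect_true(all(b$table$lower >= 0 & b$table$upper <= 1))
  # plus-adjusted bands never collapse to zero width
  expect_true(all(b$table$upper - b$table$lower > 0))
  b2 <- confidence_band(d, "alg1", grid, plus = TRUE, draws = 2e4,
                        seed = 3)
  expect_identical(b$table, b2$table)
  expect_identical(b$q, b2$q)
  # very high alpha collapses the band toward its center
  bw <- confidence_band(d, "alg1", grid, alpha = 0.999, draws = 2e4,
                        seed = 3)
  expect_true(all(bw$table$upper - bw$table$lower <
                    b$table$upper - b$table$lower))
  bd <- confidence_band_diff(d, "alg1", "alg2", grid, draws = 2e4,
                             seed = 5)
  expect_true(all(bd$table$lower >= -1 & bd$table$upper <= 1))
  expect_true(all(bd$table$lower <= bd$table$center))
})

test_that("unadjusted bands flag zero-variance grid points", {
  # a recall of exactly zero at a tiny fraction has zero plug-in variance
  d <- scored_dataset(c(rep(0, 99), 1), c(100:2, 1))
  b <- confidence_band(d, "alg1", c(0.05, 0.5), plus = FALSE,
                       draws = 1e4, seed = 1)
  expect_true(length(b$zero_variance) >= 1)
})
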