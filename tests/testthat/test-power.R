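test_that("treated rate solves the odds equation", {
  expect_equal(treated_rate(0.3, 1.0), 0.3)
  expect_equal(treated_rate(0.5, 2.0), 2 / 3)
  expect_equal(treated_rate(0.2, 3.0), 0.4286, tolerance = 1e-4)
  # definitionally: odds(p1) / odds(p0) = OR
  p1 <- treated_rate(0.37, 2.5)
  expect_equal((p1 / (1 - p1)) / (0.37 / 0.63), 2.5)
  expect_error(treated_rate(0, 2), "base_rate")
  expect_error(treated_rate(1.2, 2), "base_rate")
  expect_error(treated_rate(0.3, -1), "odds_ratio")
})

test_that("expected 2x2 counts follow the assumed rates", {
  expect_equal(unname(expected_counts(0.5, 1.0, 100, 100)),
               c(50, 50, 50, 50))
  expect_equal(unname(expected_counts(0.3, 1.0, 10, 20)), c(3, 7, 6, 14))
  e <- expected_counts(0.2, 3.0, 100, 100)
  expect_equal(e[["e11"]], 42.86, tolerance = 1e-3)
  expect_equal(e[["e11"]] + e[["e10"]], 100)
  expect_equal(e[["e01"]] + e[["e00"]], 100)
  expect_error(expected_counts(1e-12, 1, 5, 5), "degenerate")
  expect_error(expected_counts(0.3, 1, 0, 10), "group sizes")
})

test_that("log odds-ratio SE is the root sum of reciprocal counts", {
  expect_equal(se_log_or(c(100, 100, 100, 100)), 0.2)
  expect_equal(se_log_or(c(25, 25, 25, 25)), 0.4)
  expect_equal(se_log_or(c(3, 7, 6, 14)), sqrt(1/3 + 1/7 + 1/6 + 1/14))
  expect_error(se_log_or(c(0, 1, 1, 1)), "positive")
  expect_error(se_log_or(c(1, 1, 1)), "four")
})

test_that("a null odds ratio gives power equal to alpha at every size", {
  expect_equal(power_binary(0.3, 1.0, 150, 150), 0.05)
  expect_equal(power_binary(0.3, 1.0, 3000, 3000), 0.05)
  expect_identical(power_binary(0.47, 1.0, 150, 150),
                   power_binary(0.12, 1.0, 3000, 3000))
  expect_equal(power_binary(0.2, 1.0, 50, 80, alpha = 0.01), 0.01)
  expect_equal(power_relative_risk(0.3, 1.0, 200, 200), 0.05)
  expect_equal(power_two_sample_t(0, 30, 30), 0.05)
  expect_equal(power_one_sample_t(0, 45), 0.05)
})

test_that("binary power approaches 1 for large samples and large effects", {
  expect_gte(power_binary(0.3, 4.98, 5000, 5000), 0.999)
  # monotone in n
  ns <- c(20, 50, 100, 200, 500, 1000)
  p <- vapply(ns, function(n) power_binary(0.3, 1.5, n, n), numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("odds-ratio power is symmetric under OR inversion with swapped roles", {
  for (g in list(c(0.3, 2.0, 100, 140), c(0.1, 1.4, 300, 200),
                 c(0.45, 0.6, 80, 90))) {
    p1 <- treated_rate(g[1], g[2])
    expect_equal(power_binary(g[1], g[2], g[3], g[4]),
                 power_binary(p1, 1 / g[2], g[4], g[3]), tolerance = 1e-12)
  }
})

test_that("binary power matches the Monte-Carlo Wald rejection rate", {
  # moderate-to-large expected cells, where the normal reference is accurate
  grid <- list(c(0.20, 1.5, 200, 200), c(0.30, 1.2, 500, 500),
               c(0.40, 0.7, 150, 150))
  for (g in grid) {
    p_hat <- mc_power_binary(g[1], g[2], g[3], g[4], nsim = 5e4, seed = 11)
    expect_equal(power_binary(g[1], g[2], g[3], g[4]), p_hat,
                 tolerance = mc_3se(p_hat, 5e4) / max(p_hat, 0.05))
  }
})

test_that("noncentral-t powers match Monte-Carlo rejection rates", {
  p_hat <- mc_power_t2(0.5, 64, 64, nsim = 4e4, seed = 3)
  expect_equal(power_two_sample_t(0.5, 64, 64), p_hat,
               tolerance = mc_3se(p_hat, 4e4) / p_hat)
  p_hat1 <- mc_power_t1(0.3, 45, nsim = 4e4, seed = 4)
  expect_equal(power_one_sample_t(0.3, 45), p_hat1,
               tolerance = mc_3se(p_hat1, 4e4) / p_hat1)
})

test_that("one-sample t power reproduces the reference field levels", {
  expect_equal(power_one_sample_t(0.3, 45), 0.50, tolerance = 0.02)
  expect_equal(power_one_sample_t(0.49, 45), 0.90, tolerance = 0.02)
  expect_error(power_one_sample_t(0.3, 1), "n >= 2")
})

test_that("t power is strictly monotone in effect size and sample size", {
  d <- seq(0.1, 1.2, by = 0.1)
  p_d <- power_two_sample_t(d, 30, 30)
  expect_true(all(diff(p_d) > 0))
  ns <- c(5, 10, 20, 40, 80, 160)
  p_n <- vapply(ns, function(n) power_two_sample_t(0.4, n, n), numeric(1))
  expect_true(all(diff(p_n) > 0))
  expect_error(power_two_sample_t(0.5, 1, 1), "n1 \\+ n2")
})

test_that("relative-risk power follows its delta-method formula", {
  p_hat <- mc_power_rr(0.35, 1.2, 800, 800, nsim = 5e4, seed = 5)
  expect_equal(power_relative_risk(0.35, 1.2, 800, 800), p_hat,
               tolerance = mc_3se(p_hat, 5e4) / p_hat)
  expect_error(power_relative_risk(0.5, 2.1, 100, 100), "degenerate")
})

test_that("study_power dispatches on the meta-analytic effect measure", {
  meta_d <- list(label = "m1", measure = "d", effect = 0.45)
  study <- list(meta_label = "m1", n_group1 = 20, n_group2 = 25,
                base_rate = NA_real_)
  expect_identical(study_power(study, meta_d),
                   power_two_sample_t(0.45, 20, 25))

  meta_or <- list(label = "m1", measure = "or", effect = 1.8)
  study_b <- list(meta_label = "m1", n_group1 = 50, n_group2 = 60,
                  base_rate = 0.3)
  expect_identical(study_power(study_b, meta_or),
                   power_binary(0.3, 1.8, 50, 60))

  meta_rr <- list(label = "m1", measure = "rr", effect = 1.3)
  expect_identical(study_power(study_b, meta_rr),
                   power_relative_risk(0.3, 1.3, 50, 60))

  # a study under a null meta-analysis has power alpha whatever its size
  apoe <- list(label = "m1", measure = "or", effect = 1.00)
  for (n in c(30, 150, 3000))
    expect_equal(study_power(list(meta_label = "m1", n_group1 = n,
                                  n_group2 = n, base_rate = 0.48), apoe),
                 0.05)
  expect_equal(study_power(list(meta_label = "m1", n_group1 = 20,
                                n_group2 = 20, base_rate = NA),
                           list(label = "m1", measure = "d", effect = 0)),
               0.05)

  expect_error(study_power(study, meta_or), "base rate")
  expect_error(study_power(list(meta_label = "other", n_group1 = 5,
                                n_group2 = 5), meta_d),
               "does not belong")
})
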