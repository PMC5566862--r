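test_that("single-component fit has the closed-form regularized solution", {
  x <- withr_seed(1, rnorm(200, 0.4, 0.1))
  fit <- gmm(x, 1, seed = 2)
  expect_equal(fit$means, mean(x))
  expect_equal(fit$variances,
               stats::var(x) * (length(x) - 1) / length(x) + 0.001)
  expect_equal(fit$weights, 1)
  expect_true(fit$converged)
})

test_that("two-component parameters are recovered on simulated data", {
  x <- withr_seed(7, c(rnorm(200, 0.1, 0.02), rnorm(200, 0.8, 0.05)))
  fit <- gmm(x, 2, seed = 3)
  expect_lt(max(abs(fit$means - c(0.1, 0.8))), 0.02)
  expect_lt(max(abs(fit$weights - 0.5)), 0.05)
  expect_false(is.unsorted(fit$means))
})

test_that("the penalized objective is non-decreasing in every EM run", {
  for (s in 1:20) {
    dat <- withr_seed(s, {
      kt <- sample(1:4, 1)
      km <- runif(kt)
      ks <- runif(kt, 0.02, 0.15)
      z <- sample(kt, 300, TRUE)
      rnorm(300, km[z], ks[z])
    })
    fit <- gmm(dat, k = (s %% 5) + 1, restarts = 3, seed = s)
    expect_true(all(diff(fit$trace) >= -1e-8))
  }
})

test_that("weights normalize and variances respect the regularization floor", {
  x <- withr_seed(2, c(rnorm(60, 0.2, 0.01), 0.95))  # one isolated point
  for (k in 2:4) {
    fit <- gmm(x, k, restarts = 10, seed = k)
    expect_equal(sum(fit$weights), 1, tolerance = 1e-10)
    expect_true(all(fit$variances >= 0.001))
  }
})

test_that("without regularization collapse-prone data diverge or are flagged", {
  # five identical points: an unregularized component collapses onto them
  x <- c(rep(0.2, 5), withr_seed(3, rnorm(50, 0.7, 0.05)))
  res <- tryCatch(gmm(x, 2, lambda = 0, restarts = 5, seed = 1),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "collapse")
  } else {
    expect_gt(res$n_collapsed, 0)  # divergent restarts were flagged
  }
  # with the default floor the same data fit cleanly
  fit <- gmm(x, 2, seed = 1)
  expect_true(all(fit$variances >= 0.001))
  expect_true(fit$converged)
})

test_that("identical seeds reproduce fits exactly; components sort by mean", {
  x <- withr_seed(4, c(rnorm(100, 0.3, 0.05), rnorm(100, 0.7, 0.05)))
  f1 <- gmm(x, 3, restarts = 8, seed = 99)
  f2 <- gmm(x, 3, restarts = 8, seed = 99)
  expect_identical(coef(f1), coef(f2))
  expect_false(is.unsorted(f1$means))
  expect_error(gmm(x[1:2], 3), "at least k")
  expect_error(gmm(x, 0), "k")
})

test_that("BIC applies the 3k - 1 parameter penalty", {
  x <- withr_seed(5, rnorm(300))
  fit <- gmm(x, 2, restarts = 5, seed = 1)
  expect_equal(fit$bic, -2 * fit$loglik + 5 * log(300))
  expect_equal(gmm_bic(fit), fit$bic)
  # arithmetic reference point: loglik -100, k = 2, n = 730
  fake <- fit
  fake$loglik <- -100
  expect_equal(gmm_bic(fake, n = 730), 200 + 5 * log(730), tolerance = 1e-4)
})

test_that("BIC prefers one component on unimodal data and penalizes extras", {
  x <- withr_seed(6, rnorm(500))
  sw <- gmm_sweep(x, kmax = 3, restarts = 15, seed = 2)
  expect_equal(sw$winner_k, 1)
  expect_lt(sw$fits$k1$bic, sw$fits$k2$bic)
  # extra components never reduce the attainable log-likelihood
  logliks <- vapply(sw$fits, function(f) f$loglik, numeric(1))
  expect_true(all(diff(logliks) >= -1e-3))
})

test_that("sweep recovers a well-separated four-component mixture", {
  spec <- four_component_spec()
  x <- generate_power_mixture(spec$weights, spec$means, spec$sds, 730,
                              seed = 11)$power
  sw <- gmm_sweep(x, kmax = 6, seed = 5)
  expect_equal(sw$winner_k, 4)
  expect_identical(sw$strong_evidence, sw$delta_bic_runner_up >= 10)
  expect_equal(sw$winner$means, spec$means, tolerance = 0.03)
  expect_equal(min(sw$bic), sw$winner$bic)
})

test_that("kmeans++ seeding spreads centers by squared distance", {
  x <- c(0, 0, 0, 10, 10, 10)
  hits <- withr_seed(8, vapply(1:500, function(i) {
    cen <- kmeanspp_seed(x, 2)
    any(cen == 0) && any(cen == 10)
  }, logical(1)))
  # within-cluster distances are all zero, so the second center must come
  # from the opposite cluster every time
  expect_gte(mean(hits), 0.99)

  expect_length(withr_seed(1, kmeanspp_seed(x, 1)), 1)
  y <- c(1, 2.5, 7, 9)
  expect_setequal(withr_seed(1, kmeanspp_seed(y, 4)), y)
  expect_error(withr_seed(1, kmeanspp_seed(y, 5)), "k")
})

test_that("responsibilities are normalized posteriors", {
  x <- withr_seed(9, c(rnorm(150, 0.15, 0.03), rnorm(150, 0.85, 0.03)))
  fit <- gmm(x, 2, seed = 4)
  r <- responsibilities(fit)
  expect_equal(rowSums(r), rep(1, length(x)), tolerance = 1e-12)
  at_mean <- responsibilities(fit, fit$means)
  expect_gt(at_mean[1, 1], 0.99)
  expect_gt(at_mean[2, 2], 0.99)

  twin <- manual_gmm(c(0.5, 0.5), c(0.4, 0.4), c(0.01, 0.01))
  expect_equal(responsibilities(twin, c(0.1, 0.4, 0.9)),
               matrix(0.5, 3, 2))
})

test_that("mixture density is a proper density", {
  std <- manual_gmm(1, 0, 1)
  expect_equal(mixture_density(std, 0), dnorm(0), tolerance = 1e-4)
  grid <- seq(-8, 8, length.out = 4001)
  f <- mixture_density(std, grid)
  expect_true(all(f >= 0))
  trapz <- sum((f[-1] + f[-length(f)]) / 2 * diff(grid))
  expect_equal(trapz, 1, tolerance = 1e-3)
  expect_error(mixture_density(std, c(1, 0)), "sorted")

  bim <- manual_gmm(c(0.3, 0.7), c(0.2, 0.8), c(0.01, 0.02))
  grid2 <- seq(-1, 2, length.out = 4001)
  f2 <- mixture_density(bim, grid2)
  trapz2 <- sum((f2[-1] + f2[-length(f2)]) / 2 * diff(grid2))
  expect_equal(trapz2, 1, tolerance = 1e-3)
})

test_that("fits agree with an independent EM implementation", {
  library(mclust)
  x <- generate_power_mixture(c(0.5, 0.5), c(0.2, 0.8), c(0.06, 0.06), 500,
                              seed = 3)$power
  mine <- gmm(x, 2, lambda = 0, restarts = 20, seed = 4)
  ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  # same maximum-likelihood solution: multi-restart EM must do at least as
  # well as the reference, and land on the same parameters
  expect_gte(mine$loglik, ref$loglik - 1e-3)
  expect_equal(sort(mine$means), sort(unname(ref$parameters$mean)),
               tolerance = 1e-3)
  expect_equal(sort(mine$variances),
               sort(unname(ref$parameters$variance$sigmasq)),
               tolerance = 0.05)
})

test_that("degenerate all-identical data return a floored, flagged fit", {
  fit <- gmm(rep(0.5, 30), 2, restarts = 3, seed = 1)
  expect_true(fit$degenerate)
  expect_true(all(fit$variances >= 0.001))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-10)
})

test_that("JSON serialization round-trips a fit", {
  x <- withr_seed(10, c(rnorm(80, 0.2, 0.04), rnorm(80, 0.75, 0.06)))
  fit <- gmm(x, 2, restarts = 5, seed = 6)
  path <- tempfile(fileext = ".json")
  gmm_to_json(fit, path)
  back <- gmm_from_json(path)
  expect_equal(coef(back), coef(fit))
  expect_equal(back$loglik, fit$loglik)
  expect_equal(back$bic, fit$bic)
  expect_equal(back$seed, fit$seed)
  # restored fits still support downstream computation
  expect_equal(mixture_density(back, 0.5), mixture_density(fit, 0.5))
})

test_that("simulate draws from the fitted mixture", {
  fit <- manual_gmm(c(0.5, 0.5), c(-5, 5), c(0.25, 0.25))
  draws <- simulate(fit, 4000, seed = 1)
  expect_equal(mean(draws < 0), 0.5, tolerance = 0.05)
  expect_equal(mean(draws[draws > 0]), 5, tolerance = 0.05)
  expect_identical(simulate(fit, 10, seed = 2), simulate(fit, 10, seed = 2))
})
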