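# Independent Monte-Carlo and brute-force oracles used to cross-check the
# analytic implementations. These deliberately re-derive every quantity from
# first principles (simulated data, exhaustive enumeration) and never call
# into the code paths they verify.

# Rejection rate of the Wald log odds-ratio test over simulated 2x2 tables.
mc_power_binary <- function(p0, or, n1, n0, alpha = 0.05, nsim = 1e5,
                            seed = 1) {
  withr_seed(seed, {
    p1 <- or * p0 / (1 - p0 + or * p0)
    a <- rbinom(nsim, n1, p1)
    c_ <- rbinom(nsim, n0, p0)
    b <- n1 - a
    d <- n0 - c_
    z0 <- a == 0 | b == 0 | c_ == 0 | d == 0
    a[z0] <- a[z0] + 0.5; b[z0] <- b[z0] + 0.5
    c_[z0] <- c_[z0] + 0.5; d[z0] <- d[z0] + 0.5
    stat <- abs(log(a * d / (b * c_))) / sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    mean(stat > qnorm(1 - alpha / 2))
  })
}

# Rejection rate of the Wald log risk-ratio test.
mc_power_rr <- function(p0, rr, n1, n0, alpha = 0.05, nsim = 1e5, seed = 1) {
  withr_seed(seed, {
    p1 <- rr * p0
    a <- rbinom(nsim, n1, p1)
    c_ <- rbinom(nsim, n0, p0)
    z0 <- a == 0 | c_ == 0 | a == n1 | c_ == n0
    a[z0] <- pmin(pmax(a[z0], 0.5), n1 - 0.5)
    c_[z0] <- pmin(pmax(c_[z0], 0.5), n0 - 0.5)
    ph1 <- a / n1
    ph0 <- c_ / n0
    stat <- abs(log(ph1 / ph0)) /
      sqrt((1 - ph1) / (n1 * ph1) + (1 - ph0) / (n0 * ph0))
    mean(stat > qnorm(1 - alpha / 2))
  })
}

# Rejection rate of the pooled-variance two-sample t test on normal samples
# shifted by d standard deviations.
mc_power_t2 <- function(d, n1, n2, alpha = 0.05, nsim = 1e5, seed = 1) {
  withr_seed(seed, {
    g1 <- matrix(rnorm(n1 * nsim, mean = d), n1, nsim)
    g2 <- matrix(rnorm(n2 * nsim), n2, nsim)
    m1 <- colMeans(g1); m2 <- colMeans(g2)
    v1 <- colSums((g1 - rep(m1, each = n1))^2)
    v2 <- colSums((g2 - rep(m2, each = n2))^2)
    sp <- sqrt((v1 + v2) / (n1 + n2 - 2))
    tt <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
    mean(abs(tt) > qt(1 - alpha / 2, n1 + n2 - 2))
  })
}

# Rejection rate of the one-sample t test.
mc_power_t1 <- function(d, n, alpha = 0.05, nsim = 1e5, seed = 1) {
  withr_seed(seed, {
    g <- matrix(rnorm(n * nsim, mean = d), n, nsim)
    m <- colMeans(g)
    s <- sqrt(colSums((g - rep(m, each = n))^2) / (n - 1))
    tt <- sqrt(n) * m / s
    mean(abs(tt) > qt(1 - alpha / 2, n - 1))
  })
}

# 3 binomial standard errors of an MC rejection-rate estimate.
mc_3se <- function(p, nsim) 3 * sqrt(p * (1 - p) / nsim)

# Brute-force Mann-Whitney U: pair counting with half credit for ties.
brute_force_u <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}

# Brute-force HDI of a gmm fit: sort a very fine grid by density and accumulate
# cell mass until the target is covered; return the runs of kept cells.
brute_force_hdi <- function(fit, mass = 0.95, n_grid = 2^16) {
  sd_ <- sqrt(fit$variances)
  lo <- min(fit$means - 6 * sd_)
  hi <- max(fit$means + 6 * sd_)
  grid <- seq(lo, hi, length.out = n_grid)
  f <- mixture_density(fit, grid)
  w <- (hi - lo) / (n_grid - 1)
  ord <- order(f, decreasing = TRUE)
  cum <- cumsum(f[ord] * w)
  keep <- ord[seq_len(which(cum >= mass)[1])]
  kept <- rep(FALSE, n_grid)
  kept[keep] <- TRUE
  d <- diff(c(FALSE, kept, FALSE))
  cbind(low = grid[which(d == 1)], high = grid[which(d == -1) - 1L])
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Hand-rolled gmm object for analytic checks (a fit with known parameters).
manual_gmm <- function(weights, means, variances, n = 100L) {
  structure(list(weights = weights, means = means, variances = variances,
                 loglik = NA_real_, loglik_pen = NA_real_, bic = NA_real_,
                 converged = TRUE, n_iterations = 0L, trace = numeric(0),
                 seed = 0L, lambda = 0.001, restarts = 1L, tol = 1e-6,
                 max_iter = 1000L, n = n, k = length(weights),
                 degenerate = FALSE, x = numeric(0)),
            class = "gmm")
}

# Small well-separated four-component power mixture used across tests.
four_component_spec <- function() {
  list(weights = c(0.35, 0.30, 0.20, 0.15),
       means = c(0.06, 0.25, 0.55, 0.95),
       sds = c(0.02, 0.06, 0.08, 0.03))
}
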