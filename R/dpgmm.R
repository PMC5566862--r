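#' Dirichlet-process Gaussian mixture by truncated variational inference
#'
#' Robustness check for the BIC-selected finite mixtures: a Dirichlet-process
#' mixture of univariate Gaussians fit by mean-field variational inference
#' under a stick-breaking representation truncated at `truncation`
#' components. The mixing proportions get a DP prior with concentration
#' `concentration` (the "rich get richer" parameter: smaller values favor
#' fewer clusters); each component's mean and precision get a conjugate
#' Normal-Gamma prior. The number of components is not selected by the user:
#' superfluous components lose their expected weight during inference, and
#' `effective_k` counts those retaining expected weight above `1/n`.
#'
#' Default hyperparameters are weakly informative and data-dependent:
#' `prior_mean = mean(x)`, `prior_scale = 0.1` (pseudo-observations tying a
#' component mean to the prior mean), `prior_shape = 2`, and `prior_rate`
#' such that the prior expected component variance is a quarter of the data
#' variance.
#'
#' @param x numeric data vector (n >= 2).
#' @param truncation maximum number of represented components (>= 2).
#' @param concentration DP concentration parameter alpha (> 0).
#' @param prior_mean,prior_scale,prior_shape,prior_rate Normal-Gamma
#'   hyperparameters (mu, kappa, a, b); `NULL` picks the defaults above.
#' @param tol convergence tolerance on the relative change of the evidence
#'   lower bound (ELBO).
#' @param max_iter maximum number of coordinate-ascent sweeps.
#' @param seed seed for the random responsibility initialization.
#' @return An object of class `"dpgmm"`: `stick_weights` (expected mixing
#'   proportions, length `truncation`), `components` (data.frame of posterior
#'   summaries: `mean` and scale of each component location, posterior shape
#'   and rate of its precision, expected variance, expected count `n_eff`),
#'   `elbo`, `elbo_trace`, `effective_k`, `converged`, `n_iterations`,
#'   `seed`, and the configuration.
#' @examples
#' x <- c(rnorm(250, 0.2, 0.05), rnorm(250, 0.8, 0.05))
#' fit <- dpgmm(x, seed = 1)
#' fit$effective_k
#' @export
dpgmm <- function(x, truncation = 20, concentration = 1,
                  prior_mean = NULL, prior_scale = NULL, prior_shape = NULL,
                  prior_rate = NULL, tol = 1e-6, max_iter = 500,
                  seed = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop_domain("need at least two observations")
  if (truncation < 2) stop_domain("`truncation` must be >= 2")
  if (concentration <= 0) stop_domain("`concentration` must be positive")
  T <- as.integer(truncation)
  alpha <- concentration
  vx <- stats::var(x)
  if (vx <= 0) vx <- 1e-6
  m0 <- if (is.null(prior_mean)) mean(x) else prior_mean
  k0 <- if (is.null(prior_scale)) 0.1 else prior_scale
  a0 <- if (is.null(prior_shape)) 2 else prior_shape
  b0 <- if (is.null(prior_rate)) a0 * vx / 4 else prior_rate
  if (k0 <= 0 || a0 <= 0 || b0 <= 0)
    stop_domain("Normal-Gamma hyperparameters must be positive")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)

  # random soft initialization; symmetric fixed points are broken by noise
  # and redundant components are starved by the stick-breaking prior
  phi <- with_seed(seed, matrix(stats::rgamma(n * T, shape = 1), n, T))
  phi <- phi / rowSums(phi)

  g1 <- g2 <- numeric(T - 1)
  elbo_trace <- numeric(0)
  elbo_old <- -Inf
  converged <- FALSE
  iter <- 0L
  lp <- matrix(0, n, T)

  repeat {
    iter <- iter + 1L
    ## variational M-step
    Nt <- colSums(phi)
    sx <- colSums(phi * x)
    xbar <- ifelse(Nt > 1e-12, sx / Nt, m0)
    St <- colSums(phi * outer(x, xbar, "-")^2)
    kt <- k0 + Nt
    mt <- (k0 * m0 + Nt * xbar) / kt
    at <- a0 + Nt / 2
    bt <- b0 + 0.5 * (St + k0 * Nt * (xbar - m0)^2 / kt)
    # stick posteriors (component T takes the remaining stick)
    tail_counts <- rev(cumsum(rev(Nt)))  # sum_{s >= t} N_s
    g1 <- 1 + Nt[seq_len(T - 1)]
    g2 <- alpha + tail_counts[-1]

    ## expectations
    e_log_v <- digamma(g1) - digamma(g1 + g2)
    e_log_1mv <- digamma(g2) - digamma(g1 + g2)
    e_log_pi <- c(e_log_v, 0) + c(0, cumsum(e_log_1mv))
    e_log_tau <- digamma(at) - log(bt)
    e_tau <- at / bt

    ## variational E-step
    for (t in seq_len(T))
      lp[, t] <- e_log_pi[t] + 0.5 * (e_log_tau[t] - log(2 * pi)) -
        0.5 * (1 / kt[t] + e_tau[t] * (x - mt[t])^2)
    m <- lp[, 1]
    for (t in 2:T) m <- pmax(m, lp[, t])
    lse <- m + log(rowSums(exp(lp - m)))
    phi <- exp(lp - lse)

    ## ELBO (with the freshly updated phi, all terms in closed form)
    Nt <- colSums(phi)
    e_lik <- sum(phi * lp)                       # E[ln p(x,z | .)] pieces
    e_q_z <- sum(phi * log(pmax(phi, 1e-300)))   # E[ln q(z)]
    e_p_v <- (T - 1) * log(alpha) + (alpha - 1) * sum(e_log_1mv)
    e_q_v <- sum((g1 - 1) * e_log_v + (g2 - 1) * e_log_1mv -
                   lbeta(g1, g2))
    e_p_mt <- sum(0.5 * log(k0 / (2 * pi)) + 0.5 * e_log_tau -
                    0.5 * k0 * (1 / kt + e_tau * (mt - m0)^2) +
                    a0 * log(b0) - lgamma(a0) + (a0 - 1) * e_log_tau -
                    b0 * e_tau)
    e_q_mt <- sum(0.5 * log(kt / (2 * pi)) + 0.5 * e_log_tau - 0.5 +
                    at * log(bt) - lgamma(at) + (at - 1) * e_log_tau - at)
    elbo <- e_lik - e_q_z + e_p_v - e_q_v + e_p_mt - e_q_mt
    elbo_trace[iter] <- elbo
    if (is.finite(elbo_old) &&
        abs(elbo - elbo_old) < tol * max(1, abs(elbo))) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    elbo_old <- elbo
  }

  e_v <- g1 / (g1 + g2)
  stick <- c(e_v, 1) * cumprod(c(1, 1 - e_v))
  eff_k <- sum(stick > 1 / n)
  comp <- data.frame(
    weight = stick,
    mean = mt,
    mean_scale = 1 / sqrt(kt * at / bt),
    shape = at,
    rate = bt,
    expected_variance = bt / pmax(at - 1, 1e-9),
    n_eff = Nt
  )
  structure(list(stick_weights = stick, components = comp,
                 elbo = elbo_trace[iter], elbo_trace = elbo_trace,
                 effective_k = as.integer(eff_k), converged = converged,
                 n_iterations = iter, seed = seed, truncation = T,
                 concentration = alpha,
                 prior = c(mean = m0, scale = k0, shape = a0, rate = b0),
                 n = n),
            class = "dpgmm")
}

#' @export
print.dpgmm <- function(x, ...) {
  cat(sprintf(paste0("DP Gaussian mixture (truncation %d, alpha %g): ",
                     "%d effective component(s)\n"),
              x$truncation, x$concentration, x$effective_k))
  keep <- x$stick_weights > 1 / x$n
  comp <- x$components[keep, c("weight", "mean", "expected_variance"), drop = FALSE]
  comp <- comp[order(comp$mean), ]
  rownames(comp) <- NULL
  print(round(comp, 4))
  cat(sprintf("ELBO %.3f after %d iterations (%sconverged)\n",
              x$elbo, x$n_iterations, if (x$converged) "" else "not "))
  invisible(x)
}

#' @export
summary.dpgmm <- function(object, ...) {
  print(object)
  invisible(object)
}
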