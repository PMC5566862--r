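#' kmeans++ seeding of initial component means
#'
#' Draws `k` initial centers from the data: the first uniformly at random,
#' each subsequent one with probability proportional to its squared distance
#' to the nearest center already chosen. Uses (and advances) the current RNG
#' stream; wrap in `set.seed()` or pass `seed` to [gmm()] for reproducible
#' fits.
#'
#' @param x numeric data vector.
#' @param k number of centers, `1 <= k <= length(x)`.
#' @return Numeric vector of `k` centers (data points).
#' @export
kmeanspp_seed <- function(x, k) {
  n <- length(x)
  if (n == 0) stop_domain("`x` must be non-empty")
  if (k < 1 || k > n) stop_domain("need 1 <= k <= length(x)")
  centers <- numeric(k)
  centers[1] <- x[sample.int(n, 1L)]
  if (k > 1) {
    d2 <- (x - centers[1])^2
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j] <- x[sample.int(n, 1L)]
      } else {
        centers[j] <- x[sample.int(n, 1L, prob = d2)]
      }
      d2 <- pmin(d2, (x - centers[j])^2)
    }
  }
  centers
}

# One EM run from given centers. The M-step adds `lambda` to each component's
# weighted ML variance. That update is the exact EM step for the penalized
# likelihood
#   sum_n log sum_i pi_i exp(-lambda / (2 sigma_i^2)) N(x_n; mu_i, sigma_i^2),
# provided the E-step weights carry the same exp(-lambda / (2 sigma^2)) tilt;
# the penalized objective is then non-decreasing by the usual EM argument and
# is bounded (no likelihood singularities for lambda > 0). `loglik` reports
# the untilted data log-likelihood at the fitted parameters; `loglik_pen`
# is the penalized objective used for convergence and restart selection.
em_once <- function(x, k, centers, lambda, tol, max_iter) {
  n <- length(x)
  d2 <- outer(x, centers, function(a, b) (a - b)^2)
  assign <- max.col(-d2, ties.method = "first")
  w <- pmax(tabulate(assign, k) / n, 1e-3)
  w <- w / sum(w)
  mu <- centers
  v_all <- stats::var(x) * (n - 1) / n
  if (!is.finite(v_all) || v_all <= 0) v_all <- max(lambda, 1e-12)
  s2 <- numeric(k)
  for (j in seq_len(k)) {
    xj <- x[assign == j]
    s2[j] <- if (length(xj) > 1) stats::var(xj) * (length(xj) - 1) / length(xj)
             else v_all
    if (!is.finite(s2[j]) || s2[j] <= 0) s2[j] <- v_all
  }
  s2 <- s2 + lambda

  logd <- matrix(0, n, k)
  seq_n <- seq_len(n)
  log2pi <- log(2 * pi)
  trace <- numeric(0)
  ll_pen_old <- -Inf
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  # log-sum-exp of the k per-component columns, and the iteration's
  # penalized objective; written for speed (this is the package's hot loop)
  mix_logsumexp <- function() {
    m <- logd[cbind(seq_n, max.col(logd, ties.method = "first"))]
    e <- exp(logd - m)
    rs <- .rowSums(e, n, k)
    list(ll = sum(m) + sum(log(rs)), r = e / rs)
  }
  repeat {
    iter <- iter + 1L
    cj <- log(w) - lambda / (2 * s2) - 0.5 * (log2pi + log(s2))
    hj <- 1 / (2 * s2)
    for (j in seq_len(k)) {
      d <- x - mu[j]
      logd[, j] <- cj[j] - d * d * hj[j]
    }
    est <- mix_logsumexp()
    ll_pen <- est$ll
    if (!is.finite(ll_pen)) { diverged <- TRUE; break }
    trace[iter] <- ll_pen
    if (is.finite(ll_pen_old) &&
        (ll_pen - ll_pen_old) < tol * max(1, abs(ll_pen_old))) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_pen_old <- ll_pen
    r <- est$r
    Nk <- pmax(.colSums(r, n, k), 1e-12)
    mu <- as.vector(crossprod(x, r)) / Nk
    # centered second moment: stable when a component's spread is tiny
    for (j in seq_len(k)) {
      d <- x - mu[j]
      s2[j] <- sum(r[, j] * d * d) / Nk[j] + lambda
    }
    w <- Nk / n
    if (any(!is.finite(mu)) || any(!is.finite(s2)) || any(s2 <= 0)) {
      diverged <- TRUE
      break
    }
  }
  loglik <- if (diverged) -Inf else {
    cj <- log(w) - 0.5 * (log2pi + log(s2))
    hj <- 1 / (2 * s2)
    for (j in seq_len(k)) {
      d <- x - mu[j]
      logd[, j] <- cj[j] - d * d * hj[j]
    }
    mix_logsumexp()$ll
  }
  list(weights = w, means = mu, variances = s2, loglik = loglik,
       loglik_pen = if (diverged) -Inf else ll_pen, trace = trace,
       n_iterations = iter, converged = converged, diverged = diverged)
}

#' Fit a univariate Gaussian mixture by regularized multi-restart EM
#'
#' Fits a `k`-component Gaussian mixture to a numeric vector by
#' expectation-maximization. Each M-step adds the regularization constant
#' `lambda` (default 0.001) to every component's weighted maximum-likelihood
#' variance, which bounds the likelihood and prevents components from
#' collapsing their variance onto a single data point. `restarts`
#' independent EM runs (default 50) are started from kmeans++ draws and the
#' run with the highest penalized log-likelihood wins, ties going to the
#' lowest restart index. Components are returned sorted by mean so fits are
#' comparable across seeds.
#'
#' @param x numeric data vector, `length(x) >= k`.
#' @param k number of mixture components (>= 1).
#' @param lambda non-negative regularization added to each variance per
#'   M-step. With `lambda = 0` the likelihood is unbounded and runs that
#'   collapse are dropped (an error is raised if every restart collapses).
#' @param restarts number of kmeans++-initialized EM runs.
#' @param tol convergence tolerance on the relative change of the penalized
#'   log-likelihood.
#' @param max_iter maximum EM iterations per run.
#' @param seed master seed; fans out one RNG stream per restart, so the same
#'   seed reproduces the fit exactly.
#' @return An object of class `"gmm"` with elements `weights`, `means`,
#'   `variances` (each length `k`, sorted by mean), `loglik` (data
#'   log-likelihood), `loglik_pen` (penalized objective), `bic`, `converged`,
#'   `n_iterations`, `trace` (penalized objective per iteration of the
#'   winning run), `seed`, `lambda`, `n`, `k`, `degenerate`, `n_collapsed`
#'   (restarts dropped for likelihood divergence; only possible with
#'   `lambda = 0`), and the data `x`.
#' @examples
#' x <- c(rnorm(200, 0.15, 0.04), rnorm(200, 0.8, 0.06))
#' fit <- gmm(x, k = 2, seed = 1)
#' coef(fit)
#' @export
gmm <- function(x, k, lambda = 0.001, restarts = 50, tol = 1e-6,
                max_iter = 1000, seed = NULL) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop_domain("`x` must be finite")
  n <- length(x)
  if (k < 1) stop_domain("`k` must be >= 1")
  if (n < k) stop_domain("need at least k observations")
  if (lambda < 0) stop_domain("`lambda` must be non-negative")
  if (restarts < 1) stop_domain("`restarts` must be >= 1")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  rseeds <- fan_seeds(seed, restarts)

  best <- NULL
  n_collapsed <- 0L
  for (r in seq_len(restarts)) {
    centers <- with_seed(rseeds[r], kmeanspp_seed(x, k))
    run <- em_once(x, k, centers, lambda, tol, max_iter)
    if (run$diverged) {
      n_collapsed <- n_collapsed + 1L
      next
    }
    if (is.null(best) || run$loglik_pen > best$loglik_pen) best <- run
  }
  if (is.null(best))
    stop_domain("likelihood diverged in every restart (component collapse); ",
                "use lambda > 0")

  ord <- order(best$means)
  degenerate <- k > 1 && stats::var(x) == 0
  structure(list(
    weights = best$weights[ord] / sum(best$weights),
    means = best$means[ord],
    variances = best$variances[ord],
    loglik = best$loglik,
    loglik_pen = best$loglik_pen,
    bic = gmm_bic_value(best$loglik, k, n),
    converged = best$converged,
    n_iterations = best$n_iterations,
    trace = best$trace,
    seed = seed,
    lambda = lambda,
    restarts = restarts,
    tol = tol,
    max_iter = max_iter,
    n = n,
    k = k,
    degenerate = degenerate,
    n_collapsed = n_collapsed,
    x = x
  ), class = "gmm")
}

gmm_bic_value <- function(loglik, k, n) -2 * loglik + (3 * k - 1) * log(n)

#' Bayesian information criterion of a mixture fit
#'
#' `-2 loglik + p log(n)` with `p = 3k - 1` free parameters for a
#' k-component univariate mixture (k means, k variances, k - 1 weights).
#' Lower is better; a difference of 10 or more on this natural-log scale is
#' conventionally read as strong evidence.
#'
#' @param fit a [gmm] fit.
#' @param n sample size (defaults to the size the fit was computed on).
#' @return BIC value.
#' @export
gmm_bic <- function(fit, n = fit$n) {
  stopifnot(inherits(fit, "gmm"))
  if (n < 1) stop_domain("`n` must be >= 1")
  gmm_bic_value(fit$loglik, fit$k, n)
}

#' @export
print.gmm <- function(x, digits = 4, ...) {
  cat(sprintf("Gaussian mixture fit: k = %d, n = %d (lambda = %g)\n",
              x$k, x$n, x$lambda))
  print(round(coef(x), digits))
  cat(sprintf("logLik %.3f, BIC %.3f, %sconverged in %d iterations\n",
              x$loglik, x$bic, if (x$converged) "" else "NOT ",
              x$n_iterations))
  if (x$degenerate) cat("note: degenerate fit (zero-variance data)\n")
  invisible(x)
}

#' @export
coef.gmm <- function(object, ...) {
  cbind(weight = object$weights, mean = object$means,
        variance = object$variances)
}

#' @export
logLik.gmm <- function(object, ...) {
  structure(object$loglik, df = 3 * object$k - 1, nobs = object$n,
            class = "logLik")
}

#' @export
summary.gmm <- function(object, ...) {
  out <- list(coef = coef(object), loglik = object$loglik, bic = object$bic,
              k = object$k, n = object$n, lambda = object$lambda,
              converged = object$converged)
  class(out) <- "summary.gmm"
  out
}

#' @export
print.summary.gmm <- function(x, ...) {
  cat(sprintf("%d-component Gaussian mixture on %d observations\n", x$k, x$n))
  comp <- cbind(x$coef, sd = sqrt(x$coef[, "variance"]))
  rownames(comp) <- paste0("C", seq_len(x$k))
  print(round(comp, 4))
  cat(sprintf("logLik %.3f  BIC %.3f  lambda %g  converged %s\n",
              x$loglik, x$bic, x$lambda, x$converged))
  invisible(x)
}

#' Mixture density, responsibilities, or hard classification
#'
#' @param object a [gmm] fit.
#' @param newdata numeric vector of evaluation points; defaults to the
#'   training data.
#' @param type `"density"` for the fitted mixture density,
#'   `"responsibility"` for the n-by-k matrix of posterior component
#'   membership probabilities (rows sum to 1), `"class"` for the hard
#'   (argmax) component assignment.
#' @param ... unused.
#' @return Vector, matrix, or integer vector according to `type`.
#' @export
predict.gmm <- function(object, newdata = object$x,
                        type = c("density", "responsibility", "class"), ...) {
  type <- match.arg(type)
  x <- as.numeric(newdata)
  k <- object$k
  dens <- vapply(seq_len(k), function(j)
    object$weights[j] * stats::dnorm(x, object$means[j],
                                     sqrt(object$variances[j])),
    numeric(length(x)))
  dens <- matrix(dens, nrow = length(x), ncol = k)
  if (type == "density") return(rowSums(dens))
  tot <- rowSums(dens)
  r <- dens / tot
  # points in the far tails of every component: fall back to nearest mean
  far <- !is.finite(tot) | tot == 0
  if (any(far)) {
    r[far, ] <- 0
    nearest <- max.col(-outer(x[far], object$means, function(a, b) (a - b)^2),
                       ties.method = "first")
    r[cbind(which(far), nearest)] <- 1
  }
  if (type == "responsibility") return(r)
  max.col(r, ties.method = "first")
}

#' Per-point posterior component membership
#'
#' Convenience wrapper around `predict(fit, data, type = "responsibility")`.
#' Rows sum to one; the hard assignment used for cross-tabulations is the
#' row-wise argmax.
#'
#' @param fit a [gmm] fit.
#' @param data numeric vector (defaults to the training data).
#' @return n-by-k matrix of responsibilities.
#' @export
responsibilities <- function(fit, data = fit$x) {
  predict(fit, newdata = data, type = "responsibility")
}

#' Fitted mixture density on a grid
#'
#' @param fit a [gmm] fit.
#' @param grid sorted numeric vector of evaluation points.
#' @return Numeric vector of density values, `sum_i w_i N(x; mu_i, s2_i)`.
#' @export
mixture_density <- function(fit, grid) {
  if (is.unsorted(grid)) stop_domain("`grid` must be sorted")
  predict(fit, newdata = grid, type = "density")
}

#' @export
simulate.gmm <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    z <- sample.int(object$k, nsim, replace = TRUE, prob = object$weights)
    stats::rnorm(nsim, object$means[z], sqrt(object$variances[z]))
  })
}

#' @export
plot.gmm <- function(x, breaks = 30, main = NULL, xlab = "value", ...) {
  if (is.null(main))
    main <- sprintf("%d-component Gaussian mixture", x$k)
  h <- graphics::hist(x$x, breaks = breaks, freq = FALSE, main = main,
                      xlab = xlab, col = "grey90", border = "grey60", ...)
  lo <- min(x$means - 4 * sqrt(x$variances), min(x$x))
  hi <- max(x$means + 4 * sqrt(x$variances), max(x$x))
  grid <- seq(lo, hi, length.out = 512)
  for (j in seq_len(x$k))
    graphics::lines(grid, x$weights[j] *
                      stats::dnorm(grid, x$means[j], sqrt(x$variances[j])),
                    col = "steelblue", lty = 2)
  graphics::lines(grid, mixture_density(x, grid), col = "navy", lwd = 2)
  invisible(h)
}

#' Fit mixtures for k = 1..kmax and select by BIC
#'
#' Fits [gmm()] for every component count up to `kmax` under a shared
#' configuration and picks the fit with the lowest BIC. The BIC gap to the
#' runner-up is reported and labelled "strong" when it reaches 10 on the
#' natural-log scale.
#'
#' @inheritParams gmm
#' @param kmax largest component count to try.
#' @return An object of class `"gmm_sweep"`: list with `fits` (named list,
#'   `k1` ... `k<kmax>`), `k`, `bic`, `winner_k`, `winner` (the winning
#'   [gmm]), `delta_bic_runner_up`, `strong_evidence`, `seed`.
#' @examples
#' x <- c(rnorm(300, 0.2, 0.05), rnorm(300, 0.8, 0.05))
#' sw <- gmm_sweep(x, kmax = 4, restarts = 10, seed = 1)
#' sw$winner_k
#' @export
gmm_sweep <- function(x, kmax, lambda = 0.001, restarts = 50, tol = 1e-6,
                      max_iter = 1000, seed = NULL) {
  if (kmax < 1) stop_domain("`kmax` must be >= 1")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  kseeds <- fan_seeds(seed, kmax)
  fits <- lapply(seq_len(kmax), function(k)
    gmm(x, k, lambda = lambda, restarts = restarts, tol = tol,
        max_iter = max_iter, seed = kseeds[k]))
  names(fits) <- paste0("k", seq_len(kmax))
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  winner_k <- which.min(bic)
  delta <- if (kmax == 1) NA_real_ else sort(bic)[2] - min(bic)
  structure(list(fits = fits, k = seq_len(kmax), bic = unname(bic),
                 winner_k = as.integer(winner_k),
                 winner = fits[[winner_k]],
                 delta_bic_runner_up = unname(delta),
                 strong_evidence = isTRUE(delta >= 10),
                 seed = seed),
            class = "gmm_sweep")
}

#' @export
print.gmm_sweep <- function(x, ...) {
  cat(sprintf("BIC sweep over k = 1..%d: winner k = %d\n",
              max(x$k), x$winner_k))
  tab <- data.frame(k = x$k, BIC = round(x$bic, 2))
  print(tab, row.names = FALSE)
  if (isTRUE(is.finite(x$delta_bic_runner_up)))
    cat(sprintf("Delta BIC to runner-up: %.2f (%s evidence)\n",
                x$delta_bic_runner_up,
                if (x$strong_evidence) "strong" else "weak"))
  invisible(x)
}

#' @export
plot.gmm_sweep <- function(x, ...) {
  graphics::plot(x$k, x$bic, type = "b", xlab = "components k", ylab = "BIC",
                 main = "BIC model selection", ...)
  graphics::abline(v = x$winner_k, lty = 3)
  invisible(x)
}

#' Serialize / restore a mixture fit as JSON
#'
#' The schema carries the sorted components (weight, mean, variance), the
#' data log-likelihood, BIC, convergence state, sample size, and the fit
#' configuration (lambda, restarts, tol, max_iter, seed). The training data
#' are not serialized; a restored fit supports density, responsibility, HDI
#' and simulation computations but not `plot()` histograms.
#'
#' @param fit a [gmm] fit.
#' @param path file to write; with `path = NULL` the JSON string is
#'   returned.
#' @return `gmm_to_json`: the JSON string, invisibly when written to file.
#'   `gmm_from_json`: a [gmm] object (with empty `x`).
#' @export
gmm_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "gmm"))
  obj <- list(
    components = data.frame(weight = fit$weights, mean = fit$means,
                            variance = fit$variances),
    loglik = fit$loglik, loglik_pen = fit$loglik_pen, bic = fit$bic,
    converged = fit$converged, n_iterations = fit$n_iterations, n = fit$n,
    k = fit$k,
    config = list(lambda = fit$lambda, restarts = fit$restarts,
                  tol = fit$tol, max_iter = fit$max_iter, seed = fit$seed)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname gmm_to_json
#' @param json path to a JSON file written by [gmm_to_json()], or the JSON
#'   string itself.
#' @export
gmm_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  structure(list(
    weights = obj$components$weight,
    means = obj$components$mean,
    variances = obj$components$variance,
    loglik = obj$loglik, loglik_pen = obj$loglik_pen, bic = obj$bic,
    converged = obj$converged, n_iterations = obj$n_iterations,
    trace = numeric(0),
    seed = obj$config$seed, lambda = obj$config$lambda,
    restarts = obj$config$restarts, tol = obj$config$tol,
    max_iter = obj$config$max_iter,
    n = obj$n, k = obj$k, degenerate = FALSE, x = numeric(0)
  ), class = "gmm")
}
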