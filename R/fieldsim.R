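#' Configuration of a simulated research field
#'
#' A hypothetical field is characterized by the distribution of the effect
#' sizes its studies chase and the fraction of those effects that are real.
#' A fraction `prop_true` of effects is drawn from a Gaussian with mean
#' `effect_mean` and SD `effect_sd` truncated to positive values (the "true"
#' effects; mean 0.3 gives a typically ~50%-powered field at n = 45, mean
#' 0.49 a ~90%-powered one); the remaining effects come from a half-Gaussian
#' with mode 0 and the same SD (the "null" effects, small but nonzero).
#' Every study tests its effect with a two-sided one-sample t test of size
#' `alpha` on `n` observations.
#'
#' An alternative mode varies the sample size instead: effects are fixed at
#' `effect_mean` (or 0-mode half-Gaussian scale for null studies) and `n` is
#' drawn log-normally with median `n_median` and log-scale SD `n_sdlog`.
#'
#' @param n_sim number of simulated power estimates (default 50000).
#' @param n per-study sample size for the one-sample design (default 45).
#' @param effect_mean mean of the truncated Gaussian of true effects
#'   (0.3 "low-power" field, 0.49 "high-power" field).
#' @param effect_sd SD of both effect-size distributions (default 0.07).
#' @param prop_true fraction of studies whose effect is drawn from the
#'   true-effect distribution (1 "easy" field, 0.25 "hard" field).
#' @param alpha two-sided significance level.
#' @param seed RNG seed.
#' @param mode `"vary_effect"` (default) or `"vary_n"`.
#' @param n_median,n_sdlog sample-size law for `mode = "vary_n"`.
#' @return A list of class `"field_config"`.
#' @export
field_config <- function(n_sim = 50000, n = 45, effect_mean = 0.3,
                         effect_sd = 0.07, prop_true = 1, alpha = 0.05,
                         seed = NULL, mode = c("vary_effect", "vary_n"),
                         n_median = 45, n_sdlog = 0.4) {
  mode <- match.arg(mode)
  if (effect_sd <= 0) stop_domain("`effect_sd` must be positive")
  check_prob(prop_true, "prop_true", open = FALSE)
  check_prob(alpha, "alpha")
  if (n < 2) stop_domain("`n` must be >= 2")
  structure(list(n_sim = n_sim, n = n, effect_mean = effect_mean,
                 effect_sd = effect_sd, prop_true = prop_true, alpha = alpha,
                 seed = seed, mode = mode, n_median = n_median,
                 n_sdlog = n_sdlog),
            class = "field_config")
}

# exact truncated-normal sampling on (0, Inf) by rejection
rnorm_positive <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, draw[draw > 0])
  }
  out
}

#' Sample effect sizes for a simulated field
#'
#' A fraction `prop_true` of effects is drawn from
#' `Normal(effect_mean, effect_sd^2)` truncated (by exact rejection
#' sampling, not clipping) to positive values; the rest are half-Gaussian
#' `|Normal(0, effect_sd^2)|`. All returned effects are strictly positive.
#'
#' @param config a [field_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return list with numeric `effect_sizes` (length `n_sim`) and logical
#'   `is_true_effect`.
#' @export
sample_effect_sizes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "field_config"))
  with_seed(seed, {
    is_true <- stats::runif(config$n_sim) < config$prop_true
    eff <- numeric(config$n_sim)
    n_true <- sum(is_true)
    if (n_true > 0)
      eff[is_true] <- rnorm_positive(n_true, config$effect_mean,
                                     config$effect_sd)
    if (n_true < config$n_sim)
      eff[!is_true] <- abs(stats::rnorm(config$n_sim - n_true, 0,
                                        config$effect_sd))
    list(effect_sizes = eff, is_true_effect = is_true)
  })
}

#' Simulate the power distribution of a hypothetical field
#'
#' Draws `n_sim` effect sizes per [sample_effect_sizes()] and converts each
#' into the power of a two-sided one-sample t test ([power_one_sample_t()]).
#' Deterministic given the seed.
#'
#' @inheritParams sample_effect_sizes
#' @return An object of class `"field_sample"`: `effect_sizes`, `powers`,
#'   `is_true_effect`, `config`.
#' @examples
#' easy_low <- simulate_field(field_config(n_sim = 1000, seed = 1))
#' median(easy_low$powers)   # ~0.5
#' @export
simulate_field <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "field_config"))
  draw <- sample_effect_sizes(config, seed = seed)
  if (config$mode == "vary_effect") {
    powers <- power_one_sample_t(draw$effect_sizes, config$n, config$alpha)
  } else {
    sizes <- with_seed(if (is.null(seed)) NULL else seed + 1L,
      pmax(2, round(stats::rlnorm(config$n_sim, log(config$n_median),
                                  config$n_sdlog))))
    powers <- power_one_sample_t(draw$effect_sizes, sizes, config$alpha)
  }
  structure(list(effect_sizes = draw$effect_sizes, powers = powers,
                 is_true_effect = draw$is_true_effect, config = config),
            class = "field_sample")
}

#' Histogram and summary of a simulated field
#'
#' @param sample a [simulate_field()] result.
#' @param bins number of equal-width bins over \[0, 1\].
#' @return list with `histogram` (data.frame `bin_low`, `bin_high`, `count`;
#'   counts sum to `n_sim`), `median_power`, `mean_power`.
#' @export
summarize_field <- function(sample, bins = 20) {
  stopifnot(inherits(sample, "field_sample"))
  if (length(sample$powers) == 0) stop_domain("empty field sample")
  edges <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(pmax(findInterval(sample$powers, edges, rightmost.closed = TRUE),
                   1L), bins)
  counts <- tabulate(idx, bins)
  list(histogram = data.frame(bin_low = edges[-(bins + 1)],
                              bin_high = edges[-1], count = counts),
       median_power = stats::median(sample$powers),
       mean_power = mean(sample$powers))
}

#' @export
print.field_sample <- function(x, ...) {
  cat(sprintf(paste0("Simulated field: %d studies, n = %d, true-effect mean ",
                     "%.2f (SD %.2f), %.0f%% true effects\n"),
              x$config$n_sim, x$config$n, x$config$effect_mean,
              x$config$effect_sd, 100 * x$config$prop_true))
  cat(sprintf("  median power %.3f, mean power %.3f\n",
              stats::median(x$powers), mean(x$powers)))
  invisible(x)
}
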