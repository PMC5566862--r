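# Default per-subfield generator settings. Study counts per meta-analysis
# reproduce the built-in catalogue's composition exactly (14 + 8 + 15 + 5 +
# 3 + 4 = 49 meta-analyses; 234/198/145/65/50/38 = 730 studies; 3 genetic and
# 4 treatment null meta-analyses). Effect-size and sample-size laws are a
# calibration: they were chosen once so that the generated per-subfield
# median powers approximate the published subfield medians (genetic lowest,
# miscellaneous highest) and the pooled power histogram is multimodal with a
# low-power mode (genetic and null studies) and a pile-up near 1. They are
# plausibility settings, not ground truth about any real subfield.
default_subfield_specs <- function() {
  list(
    genetic = list(
      study_counts = c(18, 6, 4, 14, 27, 12, 6, 6, 36, 6, 53, 20, 14, 12),
      n_null = 3,
      measure_probs = c(d = 1 / 14, or = 13 / 14, rr = 0),
      effect_d = c(mean = 0.12, sd = 0.04),
      effect_log_ratio = c(mean = 0.18, sd = 0.06),
      n_meanlog = log(150), n_sdlog = 0.7,
      base_rate_range = c(0.15, 0.45)
    ),
    psychology = list(
      study_counts = c(13, 11, 56, 14, 57, 10, 11, 26),
      n_null = 0,
      measure_probs = c(d = 7 / 8, or = 1 / 8, rr = 0),
      effect_d = c(mean = 0.52, sd = 0.22),
      effect_log_ratio = c(mean = 0.75, sd = 0.20),
      n_meanlog = log(30), n_sdlog = 0.6,
      base_rate_range = c(0.2, 0.5)
    ),
    treatment = list(
      study_counts = c(6, 11, 14, 13, 8, 5, 7, 22, 2, 4, 8, 24, 10, 3, 8),
      n_null = 4,
      measure_probs = c(d = 6 / 15, or = 5 / 15, rr = 4 / 15),
      effect_d = c(mean = 0.45, sd = 0.15),
      effect_log_ratio = c(mean = 0.40, sd = 0.12),
      n_meanlog = log(40), n_sdlog = 0.7,
      base_rate_range = c(0.2, 0.5)
    ),
    imaging = list(
      study_counts = c(14, 8, 11, 24, 8),
      n_null = 0,
      measure_probs = c(d = 4 / 5, or = 1 / 5, rr = 0),
      effect_d = c(mean = 0.50, sd = 0.12),
      effect_log_ratio = c(mean = 0.60, sd = 0.20),
      n_meanlog = log(24), n_sdlog = 0.4,
      base_rate_range = c(0.2, 0.5)
    ),
    neurochemistry = list(
      study_counts = c(21, 17, 12),
      n_null = 0,
      measure_probs = c(d = 1, or = 0, rr = 0),
      effect_d = c(mean = 0.40, sd = 0.10),
      effect_log_ratio = c(mean = 0.40, sd = 0.15),
      n_meanlog = log(45), n_sdlog = 0.5,
      base_rate_range = c(0.2, 0.5)
    ),
    miscellaneous = list(
      study_counts = c(12, 5, 14, 7),
      n_null = 0,
      measure_probs = c(d = 0, or = 3 / 4, rr = 1 / 4),
      effect_d = c(mean = 0.6, sd = 0.2),
      effect_log_ratio = c(mean = 0.80, sd = 0.20),
      n_meanlog = log(90), n_sdlog = 0.6,
      base_rate_range = c(0.15, 0.4)
    )
  )
}

#' Configuration for the synthetic catalogue generator
#'
#' Describes, per subfield: the number of studies in each meta-analysis
#' (either a fixed vector `study_counts` — the default mirrors the built-in
#' catalogue — or a log-normal law via `study_count_meanlog`/`_sdlog`), the
#' number of null meta-analyses `n_null` (their true effect is exactly the
#' null value), the mix of effect measures, the laws of true effect
#' magnitudes (on the d scale and the log-ratio scale; magnitudes are drawn
#' from a positive-truncated Gaussian with a random sign), the per-group
#' log-normal sample-size law, and the base-rate range for binary measures
#' (one base rate per meta-analysis, shared by its studies).
#'
#' @param subfields named list of per-subfield specs; defaults mirror the
#'   built-in catalogue's structure (see package vignette).
#' @param alpha significance level used when recording true powers.
#' @param seed master seed.
#' @param inject_inconsistencies if `TRUE`, a few rows get deliberately
#'   corrupted CI/significance fields (to exercise [validate_catalogue()]).
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(subfields = default_subfield_specs(), alpha = 0.05,
                         seed = NULL, inject_inconsistencies = FALSE) {
  check_prob(alpha, "alpha")
  for (nm in names(subfields)) {
    sp <- subfields[[nm]]
    if (is.null(sp$study_counts) &&
        (is.null(sp$study_count_meanlog) || is.null(sp$study_count_sdlog)))
      stop_domain("subfield '", nm,
                  "' needs study_counts or a study-count law")
    if (!is.null(sp$study_counts) && any(sp$study_counts < 1))
      stop_domain("study counts must be positive")
    p <- sp$measure_probs
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
      stop_domain("measure_probs must be a probability vector")
    if (sp$effect_d[["sd"]] <= 0 || sp$effect_log_ratio[["sd"]] <= 0)
      stop_domain("effect-law SDs must be positive")
    if (!is.null(sp$n_null)) {
      n_meta <- if (!is.null(sp$study_counts)) length(sp$study_counts)
                else sp$n_meta
      if (sp$n_null > n_meta)
        stop_domain("n_null exceeds the number of meta-analyses")
    }
  }
  structure(list(subfields = subfields, alpha = alpha, seed = seed,
                 inject_inconsistencies = inject_inconsistencies),
            class = "synth_config")
}

#' Generate a synthetic catalogue with known ground truth
#'
#' Draws a full catalogue — meta-analysis records with synthesized CIs and
#' per-study design records — from a [synth_config()]. Null meta-analyses
#' receive the exact null effect (d = 0 or ratio 1), so their studies' true
#' power equals `alpha` regardless of sample size. CIs are synthesized by a
#' fixed-effect normal approximation on the analysis scale (d or log-ratio):
#' the meta-analytic SE is the inverse-variance combination of the
#' generated studies' approximate sampling variances, and the significance
#' marker is set from whether the synthesized CI excludes the null (so the
#' generated data contain no marker/CI inconsistencies unless
#' `inject_inconsistencies` is set).
#'
#' @param config a [synth_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return list with `catalogue` (a [catalogue] with studies attached) and
#'   `ground_truth` (list with data.frames `meta` — label, subfield,
#'   measure, true effect, null flag — and `studies` — design plus the true
#'   power computed by the package's own power engine).
#' @examples
#' g <- generate_catalogue(synth_config(seed = 1))
#' nrow(g$catalogue$records)       # 49
#' sum(g$catalogue$records$n_studies)  # 730
#' @export
generate_catalogue <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, generate_catalogue_impl(config))
}

generate_catalogue_impl <- function(config) {
  rec_list <- list()
  stu_list <- list()
  gt_meta <- list()
  alpha <- config$alpha
  for (sf in names(config$subfields)) {
    sp <- config$subfields[[sf]]
    counts <- sp$study_counts
    if (is.null(counts)) {
      counts <- pmax(1, round(stats::rlnorm(sp$n_meta, sp$study_count_meanlog,
                                            sp$study_count_sdlog)))
    }
    n_meta <- length(counts)
    n_null <- if (is.null(sp$n_null)) 0L else sp$n_null
    null_idx <- if (n_null > 0) sample.int(n_meta, n_null) else integer(0)
    for (i in seq_len(n_meta)) {
      label <- sprintf("%s_%02d", sf, i)
      measure <- sample(c("d", "or", "rr"), 1, prob = sp$measure_probs)
      is_null <- i %in% null_idx
      if (is_null) {
        effect <- if (measure == "d") 0 else 1
      } else if (measure == "d") {
        mag <- rnorm_positive(1, sp$effect_d[["mean"]], sp$effect_d[["sd"]])
        effect <- mag * sample(c(-1, 1), 1)
      } else {
        mag <- rnorm_positive(1, sp$effect_log_ratio[["mean"]],
                              sp$effect_log_ratio[["sd"]])
        effect <- exp(mag * sample(c(-1, 1), 1))
      }
      base_rate <- if (measure == "d") NA_real_ else
        stats::runif(1, sp$base_rate_range[1], sp$base_rate_range[2])
      # for risk ratios keep the treated rate inside (0, 1)
      if (measure == "rr" && effect * base_rate >= 0.95)
        base_rate <- 0.95 / effect * stats::runif(1, 0.5, 0.95)

      n1 <- pmax(5, round(stats::rlnorm(counts[i], sp$n_meanlog, sp$n_sdlog)))
      n2 <- pmax(5, round(stats::rlnorm(counts[i], sp$n_meanlog, sp$n_sdlog)))

      # approximate per-study sampling variance on the analysis scale
      study_var <- switch(measure,
        d = (n1 + n2) / (n1 * n2) + effect^2 / (2 * (n1 + n2)),
        or = {
          p1 <- treated_rate(base_rate, effect)
          1 / (n1 * p1) + 1 / (n1 * (1 - p1)) +
            1 / (n2 * base_rate) + 1 / (n2 * (1 - base_rate))
        },
        rr = {
          p1 <- effect * base_rate
          (1 - p1) / (n1 * p1) + (1 - base_rate) / (n2 * base_rate)
        })
      se_meta <- 1 / sqrt(sum(1 / study_var))
      center <- if (measure == "d") effect else log(effect)
      ci <- center + c(-1, 1) * stats::qnorm(0.975) * se_meta
      if (measure != "d") ci <- exp(ci)
      null_value <- if (measure == "d") 0 else 1
      significant <- ci[1] > null_value || ci[2] < null_value

      pow <- vapply(seq_len(counts[i]), function(s)
        study_power(list(n_group1 = n1[s], n_group2 = n2[s],
                         base_rate = base_rate),
                    list(measure = measure, effect = effect), alpha),
        numeric(1))

      rec_list[[label]] <- data.frame(
        label = label, n_studies = counts[i], measure = measure,
        effect = effect, ci_low = ci[1], ci_high = ci[2],
        significant = significant, subfield = sf, stringsAsFactors = FALSE)
      stu_list[[label]] <- data.frame(
        meta_label = label, n_group1 = n1, n_group2 = n2,
        base_rate = base_rate, power = pow, null = is_null,
        stringsAsFactors = FALSE)
      gt_meta[[label]] <- data.frame(
        label = label, subfield = sf, measure = measure,
        true_effect = effect, null = is_null, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec_list)
  studies_full <- do.call(rbind, stu_list)
  rownames(records) <- rownames(studies_full) <- NULL

  if (config$inject_inconsistencies) {
    d_rows <- which(records$measure == "d" & records$effect != 0)
    if (length(d_rows)) {       # CI printed on the wrong scale
      r <- d_rows[1]
      records$ci_low[r] <- abs(records$effect[r]) * 1.5
      records$ci_high[r] <- abs(records$effect[r]) * 4
    }
    sig_rows <- which(records$significant)
    if (length(sig_rows))       # marker contradicting the CI
      records$significant[sig_rows[1]] <- FALSE
  }

  cat_out <- catalogue(records,
                       studies_full[c("meta_label", "n_group1", "n_group2",
                                      "base_rate")])
  list(catalogue = cat_out,
       ground_truth = list(
         meta = do.call(rbind, c(gt_meta, list(make.row.names = FALSE))),
         studies = studies_full))
}

#' Labelled draws from a truncated Gaussian mixture of power values
#'
#' Fixture generator for mixture-recovery experiments: draws `n` values from
#' the stated Gaussian mixture, rejecting draws outside (0, 1] so every
#' value is a valid power, and returns the generating component of each
#' draw.
#'
#' @param weights mixture weights (must sum to 1).
#' @param means,sds component means and SDs.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return list with numeric `power` (in (0, 1\]) and integer `component`.
#' @examples
#' mix <- generate_power_mixture(c(0.5, 0.5), c(0.2, 0.8), c(0.05, 0.05),
#'                               n = 200, seed = 1)
#' table(mix$component)
#' @export
generate_power_mixture <- function(weights, means, sds, n, seed = NULL) {
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0))
    stop_domain("`weights` must be a probability vector")
  k <- length(weights)
  if (length(means) != k || length(sds) != k)
    stop_domain("`weights`, `means`, `sds` must have equal length")
  if (any(sds <= 0)) stop_domain("`sds` must be positive")
  if (any(stats::pnorm(1, means, sds) - stats::pnorm(0, means, sds) < 1e-3))
    stop_domain("a component has almost no mass inside (0, 1]")
  with_seed(seed, {
    z <- sample.int(k, n, replace = TRUE, prob = weights)
    x <- stats::rnorm(n, means[z], sds[z])
    bad <- which(x <= 0 | x > 1)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), means[z[bad]], sds[z[bad]])
      bad <- bad[x[bad] <= 0 | x[bad] > 1]
    }
    list(power = x, component = z)
  })
}
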