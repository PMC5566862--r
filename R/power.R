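#' Treated-group event rate implied by an odds ratio
#'
#' Solves `p1 / (1 - p1) = OR * p0 / (1 - p0)` for the treated-group event
#' probability `p1` given the control-group base rate `p0`.
#'
#' @param base_rate control-group event probability, in (0, 1). Vectorized.
#' @param odds_ratio assumed odds ratio, > 0.
#' @return Treated-group event probability in (0, 1).
#' @export
treated_rate <- function(base_rate, odds_ratio) {
  check_prob(base_rate, "base_rate")
  if (any(odds_ratio <= 0)) stop_domain("`odds_ratio` must be positive")
  odds_ratio * base_rate / (1 - base_rate + odds_ratio * base_rate)
}

#' Expected 2-by-2 counts under an assumed odds ratio
#'
#' Builds the expected counts of the group-by-outcome summary table for a
#' two-group binary-outcome design: events/non-events in the treated group
#' of size `n1` (at rate [treated_rate()]) and in the control group of size
#' `n0` (at the base rate).
#'
#' @inheritParams treated_rate
#' @param n1,n0 treated and control group sizes (>= 1).
#' @param floor smallest admissible expected cell; designs whose expected
#'   table contains a smaller cell are rejected as degenerate.
#' @return Named numeric vector `c(e11, e10, e01, e00)`: treated events,
#'   treated non-events, control events, control non-events.
#' @export
expected_counts <- function(base_rate, odds_ratio, n1, n0, floor = 1e-8) {
  if (any(n1 < 1) || any(n0 < 1)) stop_domain("group sizes must be >= 1")
  p1 <- treated_rate(base_rate, odds_ratio)
  e <- c(e11 = n1 * p1, e10 = n1 * (1 - p1),
         e01 = n0 * base_rate, e00 = n0 * (1 - base_rate))
  if (any(e < floor))
    stop_domain("degenerate design: an expected cell count falls below ", floor)
  e
}

#' First-order standard error of the log odds ratio
#'
#' Square root of the sum of the reciprocals of the four expected cell
#' counts of the 2-by-2 table.
#'
#' @param counts numeric vector of four positive cell counts (as returned by
#'   [expected_counts()]).
#' @return Positive scalar SE of `log(OR)`.
#' @export
se_log_or <- function(counts) {
  if (length(counts) != 4) stop_domain("`counts` must hold four cells")
  if (any(counts <= 0)) stop_domain("all cell counts must be positive")
  sqrt(sum(1 / counts))
}

# Two-sided power of a z-referenced statistic with standardized mean mu.
z_power <- function(mu, alpha) {
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(mu - zc) + stats::pnorm(-mu - zc)
}

#' Power of a binary-outcome study under an assumed odds ratio
#'
#' The test statistic is the log odds ratio divided by its first-order SE
#' (computed from the expected cell counts) and is referenced to the
#' standard normal distribution. With `odds_ratio = 1` the power equals
#' `alpha` exactly, for every sample size: under a null effect the power
#' statistic collapses to the type I error rate.
#'
#' This large-sample formula approximates the finite-sample rejection rate
#' of the Wald test; the approximation is accurate when expected cell counts
#' are moderate to large (roughly >= 30).
#'
#' @inheritParams expected_counts
#' @param alpha two-sided significance level, default 0.05.
#' @return Power in (0, 1).
#' @export
power_binary <- function(base_rate, odds_ratio, n1, n0, alpha = 0.05) {
  check_prob(alpha, "alpha")
  e <- expected_counts(base_rate, odds_ratio, n1, n0)
  z_power(abs(log(odds_ratio)) / se_log_or(e), alpha)
}

#' Power of a two-sample t test for a standardized mean difference
#'
#' Two-sided power from the noncentral t distribution with noncentrality
#' `d * sqrt(n1 * n2 / (n1 + n2))` and `n1 + n2 - 2` degrees of freedom.
#'
#' @param d assumed population standardized mean difference (Cohen's d).
#'   Vectorized.
#' @param n1,n2 group sizes; `n1 + n2` must be at least 3.
#' @param alpha two-sided significance level.
#' @return Power in (0, 1).
#' @export
power_two_sample_t <- function(d, n1, n2, alpha = 0.05) {
  check_prob(alpha, "alpha")
  df <- n1 + n2 - 2
  if (any(df < 1)) stop_domain("need n1 + n2 >= 3")
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  t_power(ncp, df, alpha)
}

#' Power of a one-sample t test
#'
#' Noncentrality `d * sqrt(n)`, `n - 1` degrees of freedom, two-sided.
#'
#' @param d assumed population standardized effect. Vectorized.
#' @param n sample size (>= 2).
#' @inheritParams power_two_sample_t
#' @return Power in (0, 1).
#' @export
power_one_sample_t <- function(d, n, alpha = 0.05) {
  check_prob(alpha, "alpha")
  if (any(n < 2)) stop_domain("need n >= 2")
  t_power(d * sqrt(n), n - 1, alpha)
}

# Two-sided noncentral-t power: P(|T'(df, ncp)| > t_crit).
t_power <- function(ncp, df, alpha) {
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}

#' Power of a binary-outcome study under an assumed relative risk
#'
#' Delta-method analogue of [power_binary()] for risk ratios: the treated
#' rate is `rr * base_rate`, the SE of `log(RR)` is
#' `sqrt((1 - p1) / (n1 p1) + (1 - p0) / (n0 p0))`, and the standardized
#' log risk ratio is referenced to the standard normal. Note: the source
#' power recipe details only the odds-ratio statistic; this risk-ratio
#' analogue follows the same construction and is the package's own reading.
#'
#' @inheritParams power_binary
#' @param rr assumed risk ratio; `rr * base_rate` must be below 1.
#' @return Power in (0, 1).
#' @export
power_relative_risk <- function(base_rate, rr, n1, n0, alpha = 0.05) {
  check_prob(alpha, "alpha")
  if (any(rr <= 0)) stop_domain("`rr` must be positive")
  check_prob(base_rate, "base_rate")
  p1 <- rr * base_rate
  if (any(p1 >= 1))
    stop_domain("degenerate design: treated rate rr * base_rate >= 1")
  if (any(n1 < 1) || any(n0 < 1)) stop_domain("group sizes must be >= 1")
  se <- sqrt((1 - p1) / (n1 * p1) + (1 - base_rate) / (n0 * base_rate))
  z_power(abs(log(rr)) / se, alpha)
}

#' Power of one study under its meta-analytic effect
#'
#' Dispatches on the meta-analysis' effect measure: [power_two_sample_t()]
#' for Cohen's d, [power_binary()] for odds ratios, [power_relative_risk()]
#' for risk ratios. The assumed population effect is always the
#' meta-analysis' pooled effect, never the study's own estimate (this is
#' prospective power under the meta-analytic effect, not post hoc power).
#'
#' @param study one study record: list or one-row data.frame with
#'   `n_group1`, `n_group2`, and `base_rate` (required for binary measures).
#' @param meta the matching meta-analysis record: list or one-row data.frame
#'   with `measure` and `effect` (and `label` if `study$meta_label` is set).
#' @param alpha two-sided significance level.
#' @return Power in (0, 1).
#' @seealso [catalogue_powers()] for all studies of a catalogue at once.
#' @export
study_power <- function(study, meta, alpha = 0.05) {
  study <- as.list(study)
  meta <- as.list(meta)
  if (!is.null(study$meta_label) && !is.null(meta$label) &&
      study$meta_label != meta$label)
    stop_domain("study record does not belong to this meta-analysis")
  switch(meta$measure,
    d = power_two_sample_t(meta$effect, study$n_group1, study$n_group2, alpha),
    or = {
      if (!is.numeric(study$base_rate) || !is.finite(study$base_rate))
        stop_domain("binary-outcome power requires a base rate")
      power_binary(study$base_rate, meta$effect, study$n_group1,
                   study$n_group2, alpha)
    },
    rr = {
      if (!is.numeric(study$base_rate) || !is.finite(study$base_rate))
        stop_domain("binary-outcome power requires a base rate")
      power_relative_risk(study$base_rate, meta$effect, study$n_group1,
                          study$n_group2, alpha)
    },
    stop_domain("unknown effect measure: ", meta$measure)
  )
}

#' Per-study powers for a whole catalogue
#'
#' Applies [study_power()] to every attached study record.
#'
#' @param x a [catalogue] with study records attached.
#' @param alpha two-sided significance level.
#' @return data.frame with one row per study: `meta_label`, `subfield`,
#'   `null_meta` (study belongs to a non-significant meta-analysis), and
#'   `power`.
#' @export
catalogue_powers <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "catalogue"))
  if (is.null(x$studies))
    stop_domain("catalogue carries no per-study design records; ",
                "attach a studies table or generate a synthetic catalogue")
  idx <- match(x$studies$meta_label, x$records$label)
  rec <- x$records[idx, ]
  n <- nrow(x$studies)
  pow <- numeric(n)
  for (i in seq_len(n))
    pow[i] <- study_power(x$studies[i, ], rec[i, ], alpha)
  data.frame(meta_label = x$studies$meta_label,
             subfield = rec$subfield,
             null_meta = !rec$significant,
             power = pow,
             stringsAsFactors = FALSE)
}
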