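#' Configuration for the full reanalysis
#'
#' @param alpha two-sided significance level for the power calculations.
#' @param lambda EM variance regularization (see [gmm()]).
#' @param restarts EM restarts per fit.
#' @param tol,max_iter EM convergence settings.
#' @param kmax_full largest component count for the pooled datasets
#'   (all studies; all excluding null; leave-one-subfield-out), default 15.
#' @param kmax_subfield largest component count for the per-subfield
#'   datasets, default 10 (must not exceed `kmax_full`).
#' @param hdi_mass probability mass of the reported highest-density
#'   intervals.
#' @param n_perm permutations for the subfield equivalence test.
#' @param n_sim_field simulated studies per hypothetical field (0 skips the
#'   field simulations).
#' @param seed master seed; every stage gets a seed fanned out from it.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(alpha = 0.05, lambda = 0.001, restarts = 50,
                            tol = 1e-6, max_iter = 1000, kmax_full = 15,
                            kmax_subfield = 10, hdi_mass = 0.95,
                            n_perm = 9999, n_sim_field = 50000, seed = 1) {
  if (kmax_full < kmax_subfield || kmax_subfield < 1)
    stop_domain("need kmax_full >= kmax_subfield >= 1")
  check_prob(alpha, "alpha")
  check_prob(hdi_mass, "hdi_mass")
  structure(list(alpha = alpha, lambda = lambda, restarts = restarts,
                 tol = tol, max_iter = max_iter, kmax_full = kmax_full,
                 kmax_subfield = kmax_subfield, hdi_mass = hdi_mass,
                 n_perm = n_perm, n_sim_field = n_sim_field, seed = seed),
            class = "analysis_config")
}

#' Run the full power reanalysis
#'
#' End-to-end pipeline on a catalogue with study records (real or
#' synthetic): computes every study's power under its meta-analytic effect,
#' then for each dataset — all studies, all excluding studies of null
#' meta-analyses, each subfield, and each leave-one-subfield-out complement
#' — runs a BIC selection sweep ([gmm_sweep()]), computes the
#' highest-density region of each winning fit, cross-tabulates hard
#' component assignments against subfield and null labels, runs the subfield
#' equivalence and pairwise Mann-Whitney tests, simulates the four reference
#' hypothetical fields (low/high typical power crossed with all/25% true
#' effects), and assembles a summary table of per-group medians, ranges,
#' percentiles and HDIs.
#'
#' @param x a [catalogue] with studies attached.
#' @param config an [analysis_config()].
#' @return An object of class `"power_reanalysis"`: list with `powers`
#'   (per-study data.frame), `sweeps` (named list of [gmm_sweep] results:
#'   `all`, `excluding_null`, `subfield:<name>`, `excluding:<name>`), `hdis`
#'   (HDI of each winning fit), `crosstab` (component by subfield/null
#'   counts for the pooled fit), `subfield_test`, `pairwise`
#'   (Mann-Whitney of the lowest-median subfield vs the rest),
#'   `summary_table`, `fields` (summaries of the four simulated fields),
#'   `config`.
#' @export
run_reanalysis <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "catalogue"), inherits(config, "analysis_config"))
  if (is.null(x$studies))
    stop_domain("reanalysis requires per-study records (real or synthetic)")
  powers <- catalogue_powers(x, alpha = config$alpha)

  subfields <- sort(unique(powers$subfield))
  datasets <- c(
    list(all = powers$power,
         excluding_null = powers$power[!powers$null_meta]),
    stats::setNames(
      lapply(subfields, function(s) powers$power[powers$subfield == s]),
      paste0("subfield:", subfields)),
    stats::setNames(
      lapply(subfields, function(s) powers$power[powers$subfield != s]),
      paste0("excluding:", subfields))
  )
  kmax <- ifelse(startsWith(names(datasets), "subfield:"),
                 config$kmax_subfield, config$kmax_full)

  seeds <- fan_seeds(config$seed, length(datasets) + 6L)
  sweeps <- vector("list", length(datasets))
  names(sweeps) <- names(datasets)
  for (i in seq_along(datasets)) {
    sweeps[[i]] <- gmm_sweep(datasets[[i]],
                             kmax = min(kmax[i], length(datasets[[i]]) - 1),
                             lambda = config$lambda,
                             restarts = config$restarts, tol = config$tol,
                             max_iter = config$max_iter, seed = seeds[i])
  }
  hdis <- lapply(sweeps, function(s)
    hdi(s$winner, mass = config$hdi_mass, support = c(0, 1)))

  # component-by-label cross-tabulation for the pooled fit
  win <- sweeps$all$winner
  comp <- predict(win, powers$power, type = "class")
  crosstab <- list(
    subfield = table(component = paste0("C", comp),
                     subfield = powers$subfield),
    null = table(component = paste0("C", comp),
                 null_meta = powers$null_meta)
  )

  ns <- length(datasets)
  subfield_test <- permutation_equivalence_test(
    powers$power, powers$subfield, n_perm = config$n_perm,
    seed = seeds[ns + 1L])
  med <- subfield_test$per_group_medians
  reference <- names(med)[which.min(med)]
  pairwise <- pairwise_mannwhitney(powers$power, powers$subfield, reference)

  fields <- NULL
  if (config$n_sim_field > 0) {
    specs <- list(easy_low = c(0.30, 1), easy_high = c(0.49, 1),
                  hard_low = c(0.30, 0.25), hard_high = c(0.49, 0.25))
    fields <- lapply(seq_along(specs), function(i) {
      cfg <- field_config(n_sim = config$n_sim_field,
                          effect_mean = specs[[i]][1],
                          prop_true = specs[[i]][2], alpha = config$alpha,
                          seed = seeds[ns + 1L + i])
      summarize_field(simulate_field(cfg))
    })
    names(fields) <- names(specs)
  }

  summary_table <- report_summary_table(
    powers$power, powers$subfield,
    extra = list(all = powers$power,
                 all_excluding_null = powers$power[!powers$null_meta]),
    sweeps = sweeps, hdis = hdis)

  structure(list(powers = powers, sweeps = sweeps, hdis = hdis,
                 crosstab = crosstab, subfield_test = subfield_test,
                 pairwise = pairwise, reference_subfield = reference,
                 fields = fields, summary_table = summary_table,
                 config = config),
            class = "power_reanalysis")
}

#' Summary table of power by group
#'
#' One row per group (plus optional pooled rows): median, minimum, maximum,
#' 2.5th/97.5th raw percentiles, the winning mixture's highest-density
#' region (when fits are supplied), and the group size.
#'
#' @param values power values.
#' @param labels group per value.
#' @param extra named list of additional (pooled) value vectors reported
#'   before the groups.
#' @param sweeps optional named list of [gmm_sweep] results; HDIs are pulled
#'   from `sweeps` (names `all`, `all_excluding_null` -> `excluding_null`,
#'   group `g` -> `subfield:g`).
#' @param hdis optional named list of precomputed [hdi] results aligned with
#'   `sweeps`.
#' @return data.frame with columns `group`, `n`, `median`, `min`, `max`,
#'   `p2.5`, `p97.5`, `hdi`.
#' @export
report_summary_table <- function(values, labels, extra = NULL, sweeps = NULL,
                                 hdis = NULL) {
  if (length(values) != length(labels))
    stop_domain("`values` and `labels` must have equal length")
  groups <- c(names(extra),
              names(sort(group_medians(values, labels), decreasing = TRUE)))
  get_values <- function(g) {
    if (!is.null(extra) && g %in% names(extra)) extra[[g]]
    else values[labels == g]
  }
  hdi_for <- function(g) {
    key <- switch(g, all = "all", all_excluding_null = "excluding_null",
                  paste0("subfield:", g))
    h <- hdis[[key]]
    if (is.null(h) && !is.null(sweeps) && !is.null(sweeps[[key]]))
      h <- hdi(sweeps[[key]]$winner, support = c(0, 1))
    if (is.null(h)) return(NA_character_)
    paste(apply(h$intervals, 1, function(r)
      sprintf("%.2f-%.2f", r[1], r[2])), collapse = ", ")
  }
  rows <- lapply(groups, function(g) {
    v <- get_values(g)
    q <- percentile_summary(v)
    data.frame(group = g, n = length(v), median = stats::median(v),
               min = min(v), max = max(v), p2.5 = unname(q[1]),
               p97.5 = unname(q[2]), hdi = hdi_for(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.power_reanalysis <- function(x, ...) {
  cat("Power reanalysis\n================\n")
  cat(sprintf("%d studies from %d meta-analyses; alpha = %g\n",
              nrow(x$powers), length(unique(x$powers$meta_label)),
              x$config$alpha))
  cat(sprintf("median power: %.2f (all), %.2f (excluding null)\n",
              stats::median(x$powers$power),
              stats::median(x$powers$power[!x$powers$null_meta])))
  cat(sprintf("pooled mixture: winner k = %d (Delta BIC %.1f, %s evidence)\n",
              x$sweeps$all$winner_k, x$sweeps$all$delta_bic_runner_up,
              if (isTRUE(x$sweeps$all$strong_evidence)) "strong" else "weak"))
  cat(sprintf("subfield equivalence: H = %.2f, p = %.4g\n",
              x$subfield_test$statistic, x$subfield_test$p_value))
  cat("\nSummary table:\n")
  tab <- x$summary_table
  tab[c("median", "min", "max", "p2.5", "p97.5")] <-
    round(tab[c("median", "min", "max", "p2.5", "p97.5")], 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a reanalysis report to disk
#'
#' Emits plain-text, machine-readable artifacts: `powers.csv` (per-study
#' powers), `summary_table.csv`, `sweeps.json` (per-dataset BIC curves,
#' winning components, HDIs), `tests.json` (subfield tests), and
#' `fields.csv` (histograms of the simulated fields), all under `dir`.
#'
#' @param x a [run_reanalysis()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "power_reanalysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$powers, file.path(dir, "powers.csv"), row.names = FALSE)
  utils::write.csv(x$summary_table, file.path(dir, "summary_table.csv"),
                   row.names = FALSE)
  sweeps <- lapply(names(x$sweeps), function(nm) {
    s <- x$sweeps[[nm]]
    list(dataset = nm, k = s$k, bic = s$bic, winner_k = s$winner_k,
         delta_bic_runner_up = s$delta_bic_runner_up,
         strong_evidence = s$strong_evidence, seed = s$seed,
         components = data.frame(weight = s$winner$weights,
                                 mean = s$winner$means,
                                 variance = s$winner$variances),
         hdi = list(mass = x$hdis[[nm]]$mass,
                    intervals = x$hdis[[nm]]$intervals))
  })
  writeLines(jsonlite::toJSON(sweeps, auto_unbox = TRUE, digits = NA),
             file.path(dir, "sweeps.json"))
  tests <- list(
    equivalence = list(statistic = x$subfield_test$statistic,
                       p_value = x$subfield_test$p_value,
                       n_permutations = x$subfield_test$n_permutations),
    reference_subfield = x$reference_subfield,
    pairwise = x$pairwise,
    seed = x$config$seed)
  writeLines(jsonlite::toJSON(tests, auto_unbox = TRUE, digits = NA),
             file.path(dir, "tests.json"))
  if (!is.null(x$fields)) {
    hist_df <- do.call(rbind, lapply(names(x$fields), function(nm)
      cbind(field = nm, x$fields[[nm]]$histogram)))
    utils::write.csv(hist_df, file.path(dir, "fields.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
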