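test_that("the default synthetic catalogue mirrors the built-in composition", {
  g <- generate_catalogue(synth_config(seed = 1))
  expect_equal(nrow(g$catalogue$records), 49)
  expect_equal(sum(g$catalogue$records$n_studies), 730)
  expect_equal(nrow(g$catalogue$studies), 730)
  tot <- subfield_totals(g$catalogue)
  expect_equal(unname(tot[c("genetic", "psychology", "treatment", "imaging",
                            "neurochemistry", "miscellaneous")]),
               c(234, 198, 145, 65, 50, 38))
  expect_equal(sum(g$ground_truth$meta$null), 7)
  # truly null meta-analyses are marked non-significant by construction
  null_labels <- g$ground_truth$meta$label[g$ground_truth$meta$null]
  expect_false(any(g$catalogue$records$significant[
    g$catalogue$records$label %in% null_labels]))
})

test_that("null meta-analyses produce study powers exactly equal to alpha", {
  spec <- list(only = list(study_counts = 10, n_null = 1,
                           measure_probs = c(d = 1, or = 0, rr = 0),
                           effect_d = c(mean = 0.4, sd = 0.1),
                           effect_log_ratio = c(mean = 0.3, sd = 0.1),
                           n_meanlog = log(30), n_sdlog = 0.5,
                           base_rate_range = c(0.2, 0.4)))
  g <- generate_catalogue(synth_config(subfields = spec, seed = 2))
  expect_equal(g$catalogue$records$effect, 0)
  expect_equal(g$ground_truth$studies$power, rep(0.05, 10))

  g49 <- generate_catalogue(synth_config(seed = 3))
  null_pow <- g49$ground_truth$studies$power[g49$ground_truth$studies$null]
  expect_equal(null_pow, rep(0.05, length(null_pow)))
})

test_that("ground-truth powers equal the power engine on the catalogue", {
  g <- generate_catalogue(synth_config(seed = 4))
  recomputed <- catalogue_powers(g$catalogue)
  expect_equal(recomputed$power, g$ground_truth$studies$power)
  # every truly null meta-analysis is marked non-significant (the converse
  # need not hold: a small true effect can fail to reach significance)
  truly_null <- g$ground_truth$meta$null[match(recomputed$meta_label,
                                               g$ground_truth$meta$label)]
  expect_true(all(recomputed$null_meta[truly_null]))
})

test_that("generation is seed-deterministic", {
  a <- generate_catalogue(synth_config(seed = 5))
  b <- generate_catalogue(synth_config(seed = 5))
  expect_identical(a$catalogue, b$catalogue)
  c_ <- generate_catalogue(synth_config(seed = 6))
  expect_false(identical(a$catalogue$studies$n_group1,
                         c_$catalogue$studies$n_group1))
})

test_that("the default catalogue reproduces the multimodal power landscape", {
  g <- generate_catalogue(synth_config(seed = 1))
  p <- catalogue_powers(g$catalogue)
  # a heavy low-power mode (genetic and null studies) ...
  expect_gt(mean(p$power < 0.2), 0.30)
  low <- p$power < 0.2
  expect_gt(mean(p$subfield[low] == "genetic" | p$null_meta[low]), 0.4)
  # ... and a ceiling mode of very-high-powered studies
  expect_gt(mean(p$power > 0.8), 0.03)
  # genetic studies sit lowest
  med <- group_medians(p$power, p$subfield)
  expect_equal(names(which.min(med)), "genetic")
})

test_that("study-count laws are honored when counts are not fixed", {
  spec <- list(f = list(n_meta = 12, study_count_meanlog = log(10),
                        study_count_sdlog = 0.5, n_null = 0,
                        measure_probs = c(d = 1, or = 0, rr = 0),
                        effect_d = c(mean = 0.4, sd = 0.1),
                        effect_log_ratio = c(mean = 0.3, sd = 0.1),
                        n_meanlog = log(30), n_sdlog = 0.5,
                        base_rate_range = c(0.2, 0.4)))
  g <- generate_catalogue(synth_config(subfields = spec, seed = 7))
  expect_equal(nrow(g$catalogue$records), 12)
  expect_equal(sum(g$catalogue$records$n_studies),
               nrow(g$catalogue$studies))
})

test_that("power-mixture draws stay in (0, 1] with the stated composition", {
  spec <- four_component_spec()
  mix <- generate_power_mixture(spec$weights, spec$means, spec$sds, 730,
                                seed = 8)
  expect_true(all(mix$power > 0 & mix$power <= 1))
  expect_length(mix$power, 730)
  # empirical component shares within 3 binomial SEs of the weights
  shares <- tabulate(mix$component, 4) / 730
  se <- sqrt(spec$weights * (1 - spec$weights) / 730)
  expect_true(all(abs(shares - spec$weights) <= 3 * se))

  expect_error(generate_power_mixture(c(0.7, 0.7), c(0.2, 0.8),
                                      c(0.1, 0.1), 10),
               "probability vector")
  expect_error(generate_power_mixture(1, 5, 0.01, 10), "mass inside")
  expect_identical(generate_power_mixture(1, 0.5, 0.1, 50, seed = 9),
                   generate_power_mixture(1, 0.5, 0.1, 50, seed = 9))
})

test_that("a single-component power sample selects one component by BIC", {
  mix <- generate_power_mixture(1, 0.5, 0.1, 500, seed = 10)
  sw <- gmm_sweep(mix$power, kmax = 3, restarts = 15, seed = 11)
  expect_equal(sw$winner_k, 1)
})

test_that("invalid generator configurations are rejected", {
  sp <- default_subfield_specs <- synth_config()$subfields
  sp$genetic$measure_probs <- c(d = 0.5, or = 0.2, rr = 0.2)
  expect_error(synth_config(subfields = sp), "probability vector")
  sp2 <- synth_config()$subfields
  sp2$genetic$n_null <- 99
  expect_error(synth_config(subfields = sp2), "n_null")
  sp3 <- synth_config()$subfields
  sp3$genetic$study_counts <- NULL
  expect_error(synth_config(subfields = sp3), "study")
})
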