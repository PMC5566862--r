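# powermix

Mixture modeling of statistical power distributions from meta-analyses.

## The problem

A field's statistical health is often summarized by a single number — "median
power is 21%" — computed by taking each published meta-analysis as the best
available estimate of a true effect and asking how likely each primary study
was to detect it. But a median presumes one population. If a field is really
a blend of subliteratures — tiny candidate-gene effects chased with large
samples, medium psychological effects chased with small ones, meta-analyses
whose pooled effect is indistinguishable from zero (for which "power"
degenerates to the type I error rate) — then no single central tendency
describes it, and policy conclusions drawn from one number can mislead.

`powermix` implements the full reanalysis workflow for this question, for
anyone auditing the power of a literature from its meta-analyses:

* **Per-study power** under the meta-analytic effect. For binary outcomes the
  test statistic is the log odds ratio over its first-order SE from the
  expected 2×2 counts, referenced to the standard normal: with
  `p1 = OR·p0 / (1 − p0 + OR·p0)`,

  ```
  SE = sqrt(1/e11 + 1/e10 + 1/e01 + 1/e00),   mu = |ln OR| / SE,
  power = Phi(mu − z_{a/2}) + Phi(−mu − z_{a/2})
  ```

  (an analogous delta-method form covers risk ratios). For standardized mean
  differences, power comes from the noncentral t distribution with
  `ncp = d·sqrt(n1 n2 / (n1 + n2))`. When the effect is null (OR = 1, d = 0)
  power equals α exactly, at any sample size.
* **Regularized Gaussian mixtures** for the distribution of the resulting
  powers: univariate EM with a 0.001 variance regularization added at every
  M-step (no likelihood singularities), 50 kmeans++ restarts, components
  compared by `BIC = −2 logL + (3k − 1) ln n` with ΔBIC ≥ 10 read as strong
  evidence; plus a truncated stick-breaking variational Dirichlet-process
  mixture as a model-free check on the component count.
* **Highest-density intervals** of the fitted density — possibly a union of
  disjoint intervals, the honest summary of a multimodal distribution.
* **Subfield comparisons**: permutation test of group equivalence on the
  Kruskal–Wallis statistic and pairwise Mann–Whitney U tests.
* **Hypothetical-field simulation**: the power distribution of a field with a
  given true-effect distribution and a given fraction of real effects.
* A **built-in catalogue** of 49 neuroscience meta-analyses (730 studies,
  six subfields, seven null results) and a **synthetic-catalogue generator**
  with known ground truth for validating every step.

## Worked example

```r
library(powermix)

## power of one study (150 per group) under a meta-analytic OR of 1.47
power_binary(base_rate = 0.3, odds_ratio = 1.47, n1 = 150, n0 = 150)
#> [1] 0.3502056

## 730 power values from a known 4-component mixture, then BIC selection
mix <- generate_power_mixture(weights = c(0.35, 0.30, 0.20, 0.15),
                              means = c(0.06, 0.25, 0.55, 0.95),
                              sds   = c(0.02, 0.06, 0.08, 0.03),
                              n = 730, seed = 11)
sw <- gmm_sweep(mix$power, kmax = 6, seed = 5)
sw
#> BIC sweep over k = 1..6: winner k = 4
#>  k     BIC
#>  1  340.65
#>  2  -61.15
#>  3 -423.87
#>  4 -550.05
#>  5 -530.07
#>  6 -509.81
#> Delta BIC to runner-up: 19.98 (strong evidence)

summary(sw$winner)
#> 4-component Gaussian mixture on 730 observations
#>    weight   mean variance     sd
#> C1 0.3494 0.0642   0.0016 0.0394
#> C2 0.3250 0.2447   0.0068 0.0826
#> C3 0.1900 0.5571   0.0068 0.0827
#> C4 0.1356 0.9468   0.0017 0.0417
#> logLik 311.285  BIC -550.047  lambda 0.001  converged TRUE

hdi(sw$winner, mass = 0.95, support = c(0, 1))
#> 95% highest-density region (3 intervals):
#>   [0.000, 0.396]
#>   [0.440, 0.659]
#>   [0.885, 1.000]
#> attained mass 0.9500, density threshold 0.432
```

The sweep recovers the generating component count (k = 4, with strong
ΔBIC evidence over k = 5), the component table matches the generating
weights/means, and the 95% highest-density region is a union of disjoint
intervals — the low-power, mid-power and ceiling modes — rather than one
misleading central interval.

Hypothetical fields (one-sample t tests, n = 45, effect SD 0.07):

```r
lo <- simulate_field(field_config(effect_mean = 0.30, seed = 1))
hi <- simulate_field(field_config(effect_mean = 0.49, seed = 2))
median(lo$powers)   # 0.503  — the "low power" field sits near 50%
median(hi$powers)   # 0.896  — the "high power" field sits near 90%
```

The end-to-end pipeline (`run_reanalysis()`) takes a catalogue with
per-study records — real, via the documented CSV schema in
`?read_catalogue`, or synthetic via `generate_catalogue()` — and produces
per-study powers, one BIC sweep per dataset (all studies, excluding null
meta-analyses, per subfield, leave-one-subfield-out), HDIs, component ×
subfield cross-tabulations, the subfield tests, and a machine-readable
report (`write_report()`).

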