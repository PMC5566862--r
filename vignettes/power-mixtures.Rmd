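---
title: "Methods: power from meta-analyses and mixture modeling of its distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: power from meta-analyses and mixture modeling of its distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powermix)
```

This vignette is the package's own account of its models, its tunable
parameters, its numerical choices, and the design decisions that were
genuinely open. It states no empirical claim beyond what the test suite and
`scripts/acceptance.R` compute.

## 1. Power under a meta-analytic effect

The central quantity is *prospective* power: the probability that a primary
study declares a two-sided significant result, assuming the population
effect equals the pooled effect of the meta-analysis the study belongs to.
This is not post hoc power (which would plug in the study's own estimate).

**Binary outcomes (odds ratios).** The control group has base rate $p_0$;
the assumed odds ratio fixes the treated rate
$p_1 = \mathrm{OR}\,p_0 / (1 - p_0 + \mathrm{OR}\,p_0)$. The expected 2×2
table is $e_{11} = n_1 p_1$, $e_{10} = n_1(1-p_1)$, $e_{01} = n_0 p_0$,
$e_{00} = n_0(1-p_0)$, the first-order SE of the log odds ratio is the
square root of the sum of the reciprocals of those expected counts, and the
standardized log odds ratio is referenced to the standard normal:
$$\text{power} = \Phi\!\big(\mu - z_{\alpha/2}\big) +
  \Phi\!\big(-\mu - z_{\alpha/2}\big), \qquad
  \mu = |\ln \mathrm{OR}| / \mathrm{SE}.$$
At $\mathrm{OR} = 1$ this is exactly $\alpha$ for every sample size: a power
analysis under a null effect degenerates to the type I error rate, which is
why studies from null meta-analyses pile up at 5% and carry no information
about their design.

Two caveats are deliberate. First, expected (not observed) counts: no
continuity correction, no small-sample exactness. Second, the formula is the
large-sample approximation to the Wald test's rejection rate. The test suite
verifies it against simulated-table Monte-Carlo rejection rates on grids
where expected cell counts are moderate to large (roughly $\geq 30$); at
small cell counts the true Wald rejection rate deviates from the normal
reference by up to about one percentage point, which is a property of the
approximation itself, not of the implementation.

**Risk ratios.** The source recipe names risk ratios but details only the
odds-ratio statistic. We use the direct delta-method analogue:
$p_1 = \mathrm{RR}\,p_0$ (requiring $p_1 < 1$),
$\mathrm{SE}(\ln \mathrm{RR}) = \sqrt{(1-p_1)/(n_1 p_1) + (1-p_0)/(n_0 p_0)}$,
normal reference as above. The skew of the log-RR Wald statistic makes the
normal approximation converge more slowly than for the OR; the Monte-Carlo
validation grid therefore uses larger groups ($\geq 800$).

**Standardized mean differences.** Two-sided power from the noncentral $t$
distribution: two-sample designs use
$\lambda = d\sqrt{n_1 n_2/(n_1+n_2)}$ with $n_1+n_2-2$ df (this is exact for
the pooled-variance $t$ test, and Monte-Carlo agreement is limited only by
simulation noise); one-sample designs use $\lambda = d\sqrt{n}$ with $n-1$
df. When only a total $N$ is known for a two-group study, the caller should
split it $\lceil N/2\rceil,\lfloor N/2\rfloor$ — the most conservative
symmetric allocation.

Significance level: two-sided $\alpha = 0.05$ everywhere, configurable.

## 2. The catalogue

`builtin_catalogue()` ships 49 meta-analysis records (730 primary studies;
subfields: candidate-gene association 234 studies, psychology 198, treatment
trials 145, neuroimaging 65, neurochemistry 50, miscellaneous 38; seven
pooled effects not significant at $\alpha=0.05$). Three editorial decisions:

* **The printed significance marker is authoritative.** `validate_catalogue()`
  reports rows where the CI and the marker disagree, or where a CI is on a
  scale that cannot match the effect (two Cohen's-d rows carry ratio-scale
  CIs), but nothing is ever "corrected" — the catalogue is an artifact to be
  preserved, inconsistencies included.
* The one split publication contributes separate cohort and case–control
  records (hence 49 records, not 48 publications).
* The unit-odds-ratio row carries its CI at the three-decimal precision
  available in the source's prose (0.861–1.156) rather than the table's
  two-decimal rounding.

Two source-internal discrepancies are documented rather than resolved: the
source text counts 92 studies in null meta-analyses (52 genetic + 40
treatment) while the table's unmarked rows sum to 78 (38 genetic + 40
treatment); and the miscellaneous subfield is described as two meta-analyses
but classified rows give four. The package follows the table.

Per-study design records (group sizes; base rates for binary measures) are
not part of the published summary table. Real-data runs therefore need a
user-supplied studies file (schema in `?read_catalogue`); everything else
can be exercised with the synthetic generator below. This also means the
published headline numbers that depend on the 730 real designs (overall and
subfield median powers, the four-component solution on the real powers, the
printed HDI bounds) are reproducible only with that file; the package's
validation instead demonstrates each mechanism on data with known ground
truth.

## 3. Regularized mixture model

The fitted model for a vector of powers $x_1,\dots,x_n$ is the ordinary
univariate Gaussian mixture
$p(x) = \sum_{i=1}^{k} \pi_i\, \mathcal N(x;\mu_i,\sigma_i^2)$, estimated by
EM. Unregularized mixture likelihoods are unbounded — a component can
collapse its variance onto one data point — so each M-step adds a
regularization constant $\lambda = 0.001$ to every component's weighted ML
variance (the univariate reading of "add a small value to the diagonal of
the covariance matrix").

**Why the objective stays monotone.** Adding $\lambda$ after the M-step is
*not* an innocuous tweak: against the plain log-likelihood it can move
downhill whenever a component's ML variance is comparable to $\lambda$. The
update is, however, the exact M-step of the penalized likelihood
$$\mathcal L_\lambda(\theta) \;=\; \sum_n \log \sum_i \pi_i\,
  e^{-\lambda/(2\sigma_i^2)}\, \mathcal N(x_n;\mu_i,\sigma_i^2),$$
provided the E-step responsibilities carry the same
$e^{-\lambda/(2\sigma_i^2)}$ tilt (an inverse-gamma-type penalty per
assignment). The package implements exactly this: $\mathcal L_\lambda$ is
bounded, ascends at every iteration by the standard EM argument (the test
suite asserts the full trace on hundreds of random datasets), convergence is
declared when its relative change drops below `tol = 1e-6`, and every
variance satisfies $\sigma_i^2 \ge \lambda$ by construction. The reported
`loglik` — and hence BIC — is the untilted data log-likelihood at the fitted
parameters, which is the quantity BIC approximates.

**Restarts and seeding.** 50 restarts (default) from kmeans++ draws: first
center uniform on the data, each next center with probability proportional
to squared distance from the chosen set; initial responsibilities from the
hard nearest-center assignment. The winner is the restart with the highest
penalized objective, ties to the lowest restart index. One master seed fans
out per-restart streams, so a seed reproduces a fit bit-for-bit. Components
are returned sorted by mean, making fits label-comparable across seeds.

**Degenerate inputs.** `n < k` is an error. Zero-variance data with `k > 1`
return a flagged fit with all variances at the floor. With `lambda = 0`
collapsing runs are dropped and counted (`n_collapsed`); if every restart
collapses, fitting fails with an explicit error — the behaviour the floor
exists to prevent.

**Model selection.** Fits for $k = 1..k_{\max}$ ($k_{\max} = 15$ for pooled
datasets, 10 for single subfields — smaller samples do not support more) are
compared by $\mathrm{BIC} = -2\log L + p \ln n$ with $p = 3k - 1$ free
parameters ($k$ means, $k$ variances, $k-1$ weights). Lowest BIC wins; the
gap to the runner-up is labelled strong evidence at $\ge 10$ on the natural
log scale. Fits are run on raw power values in $[\alpha, 1]$ without
transformation; the pile-up of near-certain studies at 1 is absorbed by a
narrow boundary component rather than a truncated likelihood — a deliberate
choice that keeps the model identical to the one whose BIC is reported.

## 4. Dirichlet-process robustness check

`dpgmm()` fits a truncated stick-breaking DP mixture by mean-field
variational inference: sticks $v_t \sim \mathrm{Beta}(1,\alpha)$ (truncation
$T = 20$, concentration $\alpha = 1$), conjugate Normal-Gamma priors on each
component's mean and precision. Default hyperparameters are weakly
informative and data-dependent: prior mean at the sample mean, prior scale
$\kappa_0 = 0.1$ pseudo-observations, shape $a_0 = 2$, rate set so the prior
expected component variance is a quarter of the data variance.
Responsibilities are initialized randomly (seeded): symmetric fixed points
are broken by noise and redundant components are starved by the
stick-breaking prior's rich-get-richer dynamics. The ELBO is computed in
closed form each sweep and must not decrease (asserted in tests);
`effective_k` counts components with expected weight above $1/n$. The DPGMM
is a robustness check on the BIC-selected component count — agreement is
expected to be approximate (within about one component on well-separated
data), not exact, and the concentration parameter is fixed rather than given
a gamma hyperprior.

## 5. Highest-density regions

For a multimodal density the informative 95% summary is the
highest-density region: the smallest set holding 95% of the mass, generally
a union of intervals (one per sufficiently probable mode). `hdi()` finds the
density threshold by bisection; candidate intervals are maximal grid runs
above the threshold (grid: 4096 points spanning means ±6 SD, endpoints
refined by linear interpolation of the density crossings), and interval
masses use the exact mixture CDF, not quadrature. If the attained mass
misses the target by more than 0.002 the grid is refined 8-fold once, then
the call errors rather than return an inaccurate region. With a clipping
`support` (e.g. `c(0, 1)` for powers) the region is that of the mixture
*truncated* to the support — fitted components near a boundary put real mass
outside it, and renormalizing is the only reading under which "95%" remains
true. Raw-data summaries (2.5th/97.5th percentiles) use R's default type-7
linear interpolation, everywhere.

## 6. Group comparisons

The K-group test of "is power exchangeable across subfields?" is a label
permutation test. The observed statistic is the tie-corrected
Kruskal–Wallis $H$ — chosen (the source names only "permutation test of
equivalence") as the K-group rank statistic consistent with Mann–Whitney
follow-ups; because the reference distribution is permutation-based, any
exchangeable statistic would be valid. Defaults: 9999 permutations, add-one
p-value $(1 + \#\{H^\ast \ge H\})/(1 + B)$, so $p \ge 1/(B+1)$. Pairwise
follow-ups are two-sided Mann–Whitney U tests (normal approximation with tie
correction, via `wilcox.test`), reported unadjusted by default to match the
source's reporting; a Holm flag exists. Exact p-value reproduction of the
original is not targeted (its statistic and permutation count are unstated);
the test's validity is checked instead: type I error within binomial bounds
of nominal under null label exchange, and $U$ verified against exhaustive
pair counting.

## 7. Hypothetical fields

`simulate_field()` draws `n_sim = 50000` effect sizes, converts each to
one-sample-t power at $n = 45$, $\alpha = 0.05$. A fraction `prop_true` of
effects comes from $\mathcal N(\mu_d, 0.07^2)$ truncated to $(0,\infty)$ —
$\mu_d = 0.30$ gives the ~50%-power field, $\mu_d = 0.49$ the ~90% one — and
the rest from the half-Gaussian $|\mathcal N(0, 0.07^2)|$: "null" effects
that are small but not exactly zero. Truncation is by exact rejection
sampling, never clipping (clipping would put an atom at the boundary).
Because both branches are supported on $(0,\infty)$, a "hard" field
(`prop_true = 0.25`) is by construction the 25/75 mixture of the two pure
fields' power distributions — a property the tests check with a
Kolmogorov–Smirnov comparison. Whether "~50%/~90%" refers to the median or
the mean is unspecified in the source; both are reported, and the acceptance
script uses the median. An alternative mode holds the effect fixed and draws
log-normal sample sizes instead; it is off by default.

## 8. The synthetic catalogue generator

`generate_catalogue()` emulates the statistical structure the analysis
assumes, with full ground truth: 49 meta-analyses whose per-subfield study
counts reproduce the built-in catalogue exactly (730 studies;
234/198/145/65/50/38), three genetic and four treatment meta-analyses truly
null (their studies' power is exactly $\alpha$), per-group sample sizes
log-normal per subfield, one base rate per binary meta-analysis, effect
magnitudes positive-truncated Gaussian with a random sign. CIs are
synthesized by a fixed-effect normal approximation on the analysis scale
(inverse-variance combination of the generated studies' approximate sampling
variances) and the significance marker is set from the synthesized CI, so
generated data are internally consistent; an option injects
catalogue-style inconsistencies to exercise the validator.

The default effect-size and sample-size laws are a *calibration*, chosen
once so that per-subfield median powers approximate the published subfield
ordering and levels (genetic lowest — large samples but tiny odds ratios —
miscellaneous highest) and the pooled histogram is multimodal with a heavy
low-power mode (genetic + null studies) and a pile-up near 1. They are
plausibility settings, not estimates of any real subfield. Two things the
generator deliberately does not emulate: publication bias (the source
discusses it but gives no procedure; its effect would be to inflate all
power estimates), and the real catalogue's per-study designs (not printed).
Consequently, passing tests show that the *machinery* — power formulas,
mixture recovery, selection, HDIs, tests — behaves correctly on data with
this structure; they do not certify the published numeric values that
require the real per-study file.

A second fixture, `generate_power_mixture()`, draws labelled power values
directly from a stated Gaussian mixture truncated to $(0,1]$; it is the
ground truth for the recovery experiments (e.g. the four-component spec
with means 0.06/0.25/0.55/0.95 at $n = 730$, recovered by the BIC sweep in
at least 8 of 10 seeds in the acceptance suite).

## 9. Pipeline and problem sizes

`run_reanalysis()` chains the stages: powers → 14 datasets (all; excluding
null; six subfields; six leave-one-subfield-out, which reuse the pooled
$k_{\max}$) → BIC sweep each → HDI of each winner → hard-assignment
cross-tabulations (component × subfield, component × null) → subfield tests
→ field simulations → summary table (median/min/max, raw percentiles, HDI
per group). All stage seeds fan out from one master seed; identical
configuration yields byte-identical reports (`write_report()` emits CSV +
JSON). The interface of the package is R functions plus this vignette; the
report files are the machine-readable surface.

Default problem sizes are the analysis-scale ones (730 powers, $k_{\max}$
15/10, 50 restarts, 9999 permutations, 50,000 field draws). The test suite
exercises end-to-end runs at reduced sizes (e.g. $k_{\max} = 3$, 4 restarts,
199 permutations) and keeps full scale where the claim being checked is
scale-dependent: component recovery at $n = 730$, the 50,000-draw field
medians, 200-replicate type-I-error calibration. These sizes are the
package's chosen validation design.

## 10. Known limitations

* The binary-outcome power formulas are large-sample normal approximations;
  at small expected cell counts they can differ from the exact Wald
  rejection rate by about a percentage point (see §1).
* BIC consistency for mixtures is asymptotic; on weakly separated components
  at $n$ in the hundreds the selected $k$ is conservative (this
  is the intended behaviour of the regularized fit and of BIC, not a bug).
* The DPGMM check is qualitative; variational inference underestimates
  posterior spread and its effective component count depends mildly on the
  hyperparameters above.
* Real-data reproduction of the published headline medians/HDIs requires the
  original per-study design file, which the package accepts but cannot ship.
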