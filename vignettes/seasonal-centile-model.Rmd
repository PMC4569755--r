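---
title: "Seasonal centile curves for serum 25(OH)D: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal centile curves for serum 25(OH)D: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdcentile)
```

## The problem

Serum 25-hydroxyvitamin D (25(OH)D) is the standard marker of vitamin D
status, and it oscillates strongly with the seasons: at mid-European
latitudes the population mean peaks in late summer and bottoms out in
late winter. A single measurement taken in February and one taken in
August are therefore not comparable, and fixed clinical cutoffs ignore
this. A reference-curve approach — the same idea as pediatric growth
charts — solves the comparability problem: instead of asking "is this
value above 50 nmol/L?", we ask "where does this value sit within the
reference population *on this date*, for this sex and BMI?".

`vitdcentile` implements such a population-based centile model, bundles
a published coefficient set estimated on a Swiss adult cohort measured
by LC-MS/MS, and provides the surrounding machinery: refitting on new
cohorts, cross-assay calibration, goodness-of-fit validation, and a
synthetic cohort generator so the whole pipeline is testable without
access to any individual-level data.

## The model

Let $y$ be 25(OH)D in nmol/L. On the square-root scale the distribution
is approximately Gaussian with constant variance, so the model is an
ordinary linear regression for $\sqrt{y}$:

$$
\sqrt{y} = \beta_0
 + \beta_1 \sin\theta + \beta_2 \cos\theta
 + \beta_3 \sin 2\theta + \beta_4 \cos 2\theta
 + \beta_5\, t(\mathrm{BMI}) + \beta_6\, t(\mathrm{BMI})^2
 + \beta_7\, I_{\mathrm{male}} I_{\mathrm{BMI}<25}\,
   \bigl(t(\mathrm{BMI}) - t(25)\bigr)^2
 + \beta_8\, I_{\mathrm{female}} \sin\theta
 + \beta_9\, I_{\mathrm{female}} \cos\theta
 + \varepsilon,
$$

with $\theta = 2\pi(\mathrm{day}-1)/365$, $t(x) = -1/\sqrt{x}$, and
$\varepsilon \sim N(0, \sigma_\varepsilon^2)$.

Key ingredients:

* **Two harmonic pairs.** The annual sine–cosine pair is the classical
  cosinor term; the semi-annual pair allows the interval between the
  seasonal minimum and maximum to differ from six months. The annual
  pair is equivalent to the amplitude–phase form
  $\beta_1'\sin(\theta + \beta_2')$ with
  $\beta_1 = \beta_1'\cos\beta_2'$, $\beta_2 = \beta_1'\sin\beta_2'$; a
  property test confirms the two parameterisations give identical means.
* **Inverse square-root BMI.** $t(x) = -1/\sqrt{x}$ is increasing and
  concave, damping the leverage of very obese participants; it enters
  linearly and quadratically.
* **A male-only low-BMI spline term.** Below BMI 25 the male mean bends
  away; the term $(t(\mathrm{BMI}) - t(25))^2$ with a strict
  $\mathrm{BMI} < 25$ indicator is zero in value *and* first difference
  at the knot, so the predicted mean is continuous and smooth there.
  At exactly BMI 25 the regressor is zero under either a strict or weak
  inequality, so the convention only matters for refits; the strict form
  is used and boundary-tested.
* **Sex-by-season interaction.** The female annual harmonic is shifted,
  which moves the female seasonal minimum about a week later than the
  male one while both sexes share the same maximum date.

Because the transformed-scale model is homoscedastic Gaussian, every
centile is closed-form: the $\alpha$ centile is
$(\hat y + z_\alpha \sigma_\varepsilon)^2$ where $\hat y$ is the fitted
sqrt-scale mean, and a measurement $y$ inverts to the population
quantile $\Phi\bigl((\sqrt{y} - \hat y)/\sigma_\varepsilon\bigr)$. The
two maps are exact inverses of each other.

The bundled reference model (`published_vitd_model()`) stores the
coefficient vector exactly at the precision at which it was reported,
together with $\sigma_\varepsilon = 1.36$ sqrt(nmol/L), since the
reference worked examples validate at that precision.

## Conventions and numerical choices

* **Calendar.** January 1 is day 1 and the angle is
  $2\pi(\mathrm{day}-1)/365$; the model has no 366-day mode. February
  29 is accepted and mapped to index 60 (shared with March 1), so
  leap-year dates never error and later dates keep their non-leap index.
* **Clamping.** At extreme small $\alpha$ and high BMI the sqrt-scale
  centile $\hat y + z_\alpha\sigma_\varepsilon$ can go negative;
  squaring it naively would *increase* the reported centile as $\alpha$
  decreases. The implementation clamps at zero before squaring and
  warns, preserving monotonicity in $\alpha$.
* **Probabilities are probabilities.** `alpha` must lie in (0, 1);
  percent-scale inputs are rejected rather than silently divided by 100.
* **Seasonal extrema** are searched over integer days 1–365 (matching
  calendar-date reporting) rather than by solving the continuous
  stationarity equation; ties break to the smallest index. The search
  confirms — rather than assumes — that both sexes share the same
  maximum date under the bundled coefficients.

## Refitting and model choice

`vitd_fit()` is ordinary least squares on $\sqrt{y}$ via QR. The
residual SD uses the unbiased denominator $n - k$ with $k$ the number of
regression coefficients; at cohort sizes in the thousands the choice is
numerically negligible, but it is fixed and documented. Rank-deficient
designs (a single-sex cohort with sex interactions, for instance) raise
an error naming the collinear columns. Rows with a missing outcome are
an error; rows with missing covariates are dropped listwise with a
logged count.

`vitd_bic()` uses the Gaussian profile-likelihood form
$n\ln(\mathrm{RSS}/n) + k\ln n$ with the variance parameter counted in
$k$ and the constant terms dropped — only BIC *differences* between
candidates on the same data are consumed, so neither choice affects the
ranking of equal-$n$ fits except through $k$, and both are stated here
because they are genuinely open conventions.

The candidate set for `vitd_select()` is configuration, not code: the
default list covers one versus two harmonic pairs, the BMI terms, the
low-BMI spline, sex main effect, sex-by-season, and age main/interaction
effects, without claiming to replicate any particular historical model
search. Ties break deterministically by candidate order.

## Cross-assay calibration

Different 25(OH)D assays (LC-MS/MS versus immunoassays) differ
systematically. `pb_fit()` implements the classic Passing–Bablok
structural regression: the slope is the shifted median of all pairwise
slopes — robust, symmetric in both axes, and free of error-distribution
assumptions. Conventions, all from the classic formulation: slopes
exactly $-1$ are discarded; x-ties with equal y are dropped and x-ties
with unequal y rank as signed infinities at the extremes; the even-count
median is the midpoint of the two central order statistics; confidence
intervals use the rank-based normal approximation with
$w = z_{0.975}\sqrt{n(n-1)(2n+5)/18}$ (not bootstrap), the standard for
method-comparison reporting. Shifted ranks that would run past the ends
of the slope list are pinned to the extreme order statistics; this can
only occur on tiny, noisy, or downward-sloping inputs outside the
estimator's intended domain. The bundled line
(`published_calibration()`, intercept 8.71, slope 0.86) stores the
reported values; note its fixed point $8.71/(1-0.86) \approx 62.2$
nmol/L, the concentration at which the two assays agree.

A calibration line carries a `scale` tag (`original` or `sqrt`) and
`pb_apply()` refuses a mismatch: a line fitted on sqrt-transformed
values must be applied to sqrt-transformed values. Both scales are
supported because method-comparison lines are reported on the original
scale while the replication pipeline applies the correction on the
sqrt scale; `vitd_validate()` composes the appropriate transform
automatically.

## Validation by predicted-quantile uniformity

If the model is correct, the predicted quantiles
$\Phi\bigl((\sqrt{y_i} - \hat y_i)/\sigma_\varepsilon\bigr)$ of a cohort
are uniform on (0, 1). `vitd_validate()` reports the one-sample
Kolmogorov–Smirnov statistic (by the exact order-statistic formula), a
nonparametric bootstrap percentile interval (the interval method is a
package choice — B = 1000 resamples, seeded, labelled as bootstrap),
a 20-bin histogram (bin count is a free display choice), and the
observed fractions below chosen nominal centiles. No composite-null KS
p-values are attempted; the statistic and interval are descriptive, as
is standard for this diagnostic.

## The synthetic cohort generator

`cohort_spec()` / `generate_cohort()` emulate the data-generating
assumptions of the analysis: sex Bernoulli(0.493 male); BMI and age from
truncated normals (25.6 ± 4.1 on 18–40 kg/m²; 49.8 ± 8.5 on 35–65 y —
the hard ranges sit near the 1st/99th percentiles of the untruncated
laws, so truncation is the natural reading of the stated bounds);
measurement dates by monthly weights (uniform by default,
user-configurable, since real recruitment is seasonally uneven) then
uniform within the month; and
$\sqrt{y} = \hat y + N(0, \sigma_\varepsilon)$, clamped at zero and
squared. A configurable 3.9% of rows are flagged as supplemented and
shifted by +1.23 on the sqrt scale (about the gap between supplemented
and unsupplemented group means) — a fixture choice for exercising the
exclusion filter, not an estimate of a supplementation effect.
`apply_inclusion_criteria()` applies the closed intervals 35–65 years
and 18–40 kg/m² and drops supplemented rows unless asked to keep them,
logging each excluded row once under the first criterion it fails.

What the generator deliberately does **not** emulate: the joint
sex-by-BMI distribution (marginals are independent given sex unless
configured otherwise), seasonal recruitment imbalance (unless weights
are supplied), assay-specific measurement error beyond the homoscedastic
sqrt-scale residual, and any within-person longitudinal correlation.
Passing tests on generated cohorts therefore demonstrates the
*internal* consistency of the pipeline — estimator recovers generator —
not the adequacy of the model for any particular real population.

## Problem sizes used by the test suite

Parameter-recovery checks refit cohorts of n = 5000 across 200 seeded
replicates (each coefficient within 3 estimated SEs; residual SD in
[1.30, 1.42]); the uniformity suite scores 500 cohorts of n = 1000
against the asymptotic 5% KS bound (accepting a 2–10% exceedance rate);
calibration coverage uses 200 replicates of 60 pairs. These sizes give
stable pass/fail behaviour at sub-minute runtimes and are stated here so
they can be scaled in either direction deliberately rather than
implicitly.

## Known limitations

* The centile curves describe a *population* at a fixed latitude and
  period; using them to project an individual's value to another date
  assumes within-person seasonal correlation of 1, which is optimistic.
* The reference coefficients apply to adults 35–65 with BMI 18–40
  measured on the LC-MS/MS scale; outside that envelope (children,
  elderly, other latitudes, uncalibrated assays) they extrapolate.
* $\beta_7$ is reported with no decimals, so the low-BMI male bend is
  stored at lower relative precision than the other coefficients; the
  bundled value is as printed.
* The model is homoscedastic Gaussian on the sqrt scale by construction;
  cohorts violating that (heavy supplementation, mixed assays without
  calibration) will show up in the uniformity diagnostics rather than
  being corrected automatically.
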