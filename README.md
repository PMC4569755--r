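# vitdcentile

Seasonal centile curves for serum 25-hydroxyvitamin D (25(OH)D).

Serum 25(OH)D, the standard marker of vitamin D status, swings strongly
with the seasons — at mid-European latitudes the population mean peaks in
late August and bottoms out in mid-March. A measurement interpreted against
a fixed cutoff therefore means something different in winter than in
summer. `vitdcentile` takes the reference-curve approach familiar from
growth charts: it models the *distribution* of 25(OH)D as a function of
calendar date, sex and BMI, so that any measurement can be placed at its
population quantile regardless of when it was taken. It is intended for
clinical chemists, epidemiologists, and anyone building or validating
seasonally adjusted reference intervals.

## The model

A linear regression on square-root transformed 25(OH)D (the transform
makes residuals approximately Gaussian and homoscedastic), with
$\theta = 2\pi(\mathrm{day}-1)/365$ and $t(x) = -1/\sqrt{x}$:

$$
\sqrt{y} = \beta_0 + \beta_1\sin\theta + \beta_2\cos\theta
 + \beta_3\sin 2\theta + \beta_4\cos 2\theta
 + \beta_5 t(\mathrm{BMI}) + \beta_6 t(\mathrm{BMI})^2
 + \beta_7 I_{\mathrm{male}}I_{\mathrm{BMI}<25}\bigl(t(\mathrm{BMI})-t(25)\bigr)^2
 + \beta_8 I_{\mathrm{female}}\sin\theta
 + \beta_9 I_{\mathrm{female}}\cos\theta + \varepsilon .
$$

The $\alpha$ centile on the nmol/L scale is
$(\hat y + z_\alpha\,\sigma_\varepsilon)^2$, and a measurement $y$ maps to
the population quantile $\Phi\bigl((\sqrt{y}-\hat y)/\sigma_\varepsilon\bigr)$.
A reference coefficient set estimated on a Swiss adult population cohort
(LC-MS/MS assay, ages 35–65, BMI 18–40) is bundled as
`published_vitd_model()`.

Around this core the package provides:

* refitting on new cohorts and BIC-based candidate comparison
  (`vitd_fit()`, `vitd_select()`),
* Passing–Bablok method-comparison regression for cross-assay
  calibration (`pb_fit()`, `pb_apply()`),
* goodness-of-fit validation by predicted-quantile uniformity with a
  Kolmogorov–Smirnov statistic and bootstrap CI (`vitd_validate()`),
* a synthetic cohort generator matching the reference population's
  covariate structure (`cohort_spec()`, `generate_cohort()`,
  `apply_inclusion_criteria()`),
* a command-line tool (`vitd_cli()`; installed script in `inst/cli/vitd`).

See the methods vignette (`vignettes/seasonal-centile-model.Rmd`) for the
model assumptions, conventions, and limitations.

## Worked example

```r
library(vitdcentile)
m <- published_vitd_model()

# Median 25(OH)D for a woman with BMI 20 measured on August 22:
predict(m, data.frame(sex = "F", bmi = 20, date = "2005-08-22"))
#> [1] 69.14667

# A man with BMI 25 measures 60 nmol/L on January 1 -- which quantile?
predict(m, data.frame(sex = "M", bmi = 25, day = 1, vitd = 60),
        type = "quantile")
#> [1] 0.885922

# Seasonal extremes for women (day-of-year indices):
extremum_days(m, "F")
#> day_min day_max
#>      77     234
```

So the model's median for that woman in late August is 69.1 nmol/L; the
man's winter measurement of 60 nmol/L — numerically "insufficient" by the
usual 75 nmol/L cutoff — actually sits at the 88.6th percentile of his
reference population on that date. Women's predicted levels bottom out on
day 77 (March 18) and peak on day 234 (August 22); men share the same peak
but reach their minimum a week earlier (day 70, March 11).

The same numbers from the shell:

```sh
$ Rscript inst/cli/vitd quantile --sex M --bmi 25 --date 2005-01-01 --value 60
0.886
$ Rscript inst/cli/vitd centile --sex F --bmi 20 --date 2005-08-22 --alpha 0.5
69.1
```

A full pipeline on synthetic data — generate a cohort from the reference
model, apply the inclusion filters, refit, and validate:

```r
co   <- generate_cohort(cohort_spec(n = 2000), seed = 42)
kept <- apply_inclusion_criteria(co)$cohort   # drops supplemented rows
vitd_fit(kept)
#> Seasonal 25(OH)D regression fit (sqrt scale)
#>   n = 1907  terms: harmonic1 + harmonic2 + tbmi + tbmi2 + male_lowbmi_spline + sex_harmonic1
#>   sigma_eps = 1.349  R^2 = 0.301  BIC = 1215.52
#>   ...

vitd_validate(m, kept, B = 500, seed = 1)
#> Predicted-quantile uniformity check (n = 1907 )
#>   KS statistic: 0.024  (95% bootstrap CI [0.016; 0.054])
#>   below the 3% centile: 3.1% observed
#>   below the 10% centile: 10.2% observed
```

The refit recovers the generating structure (residual SD 1.349 against a
generating 1.36), and the predicted quantiles of a self-generated cohort
are close to uniform, as they should be under a correct model.

## File formats

* **Cohort CSV**: columns `sex` (M/F), `age`, `bmi`, `date` (ISO-8601) or
  `day` (1–365), `vitd_nmol_l`, `supplemented` (0/1/NA). Example:
  `inst/extdata/toy_cohort.csv`.
* **Model file**: flat key-value JSON with `beta0`…`beta9`, `sigma_eps`,
  `provenance`, `schema_version` (`inst/extdata/published-model.json`).
* **Calibration file**: same document style plus a `scale` tag
  (`inst/extdata/published-calibration.json`).
* **Curve table CSV**: `day, sex, bmi, alpha, centile` from
  `export_curves()` or the `curves` subcommand.

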