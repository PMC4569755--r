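Package: vitdcentile
Title: Seasonal Centile Curves for Serum 25-Hydroxyvitamin D
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-based seasonal reference curves for serum
    25-hydroxyvitamin D (25(OH)D). Implements a two-harmonic (cosinor)
    linear model on square-root transformed 25(OH)D with an inverse
    square-root BMI transform and sex interactions; predicts any centile
    of the 25(OH)D distribution for a given sex, BMI and calendar date,
    and inverts a measurement into a population quantile. Includes
    refitting and BIC-based candidate selection on new cohorts,
    Passing-Bablok method-comparison regression for cross-assay
    calibration, goodness-of-fit validation by predicted-quantile
    uniformity (Kolmogorov-Smirnov statistic with bootstrap confidence
    interval), and a synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
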