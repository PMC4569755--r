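# Synthetic cohorts with the statistical structure the analysis assumes:
# Gaussian errors on the sqrt scale around the seasonal model, sex and
# covariate marginals matching a Swiss population-based cohort.

#' Specification of a synthetic cohort
#'
#' Defaults emulate the reference population: 49.3% male; BMI from a
#' normal(25.6, 4.1) truncated to 18..40 kg/m^2 (the stated range sits
#' near the 1st and 99th percentiles); age normal(49.8, 8.5) truncated to
#' 35..65 years; measurement dates spread over the year by monthly
#' weights; 3.9% supplemented, shifted upward by 1.23 on the sqrt scale
#' (about the gap between supplemented and non-supplemented means).
#'
#' @param n cohort size.
#' @param p_male probability of male sex.
#' @param bmi_mean,bmi_sd,bmi_range BMI marginal (truncated normal).
#' @param age_mean,age_sd,age_range age marginal (truncated normal).
#' @param day_weights 12 nonnegative monthly sampling weights.
#' @param model generating [vitd_model()] (its `sigma_eps` is the residual
#'   SD used).
#' @param supplement_fraction fraction of supplemented participants.
#' @param supplement_shift sqrt-scale mean offset for supplemented rows.
#' @param seed optional default seed used by [generate_cohort()].
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n = 5000L, p_male = 0.493,
                        bmi_mean = 25.6, bmi_sd = 4.1,
                        bmi_range = c(18, 40),
                        age_mean = 49.8, age_sd = 8.5,
                        age_range = c(35, 65),
                        day_weights = rep(1, 12),
                        model = published_vitd_model(),
                        supplement_fraction = 0.039,
                        supplement_shift = 1.23,
                        seed = NULL) {
  chk <- function(ok, field) {
    if (!ok) stop("invalid cohort spec field: '", field, "'", call. = FALSE)
  }
  chk(is.numeric(n) && length(n) == 1L && n >= 1, "n")
  chk(is.numeric(p_male) && p_male >= 0 && p_male <= 1, "p_male")
  chk(is.numeric(bmi_sd) && bmi_sd > 0, "bmi_sd")
  chk(length(bmi_range) == 2L && bmi_range[1] < bmi_range[2], "bmi_range")
  chk(is.numeric(age_sd) && age_sd > 0, "age_sd")
  chk(length(age_range) == 2L && age_range[1] < age_range[2], "age_range")
  chk(length(day_weights) == 12L && all(day_weights >= 0) &&
        sum(day_weights) > 0, "day_weights")
  chk(inherits(model, "vitd_model"), "model")
  chk(is.numeric(supplement_fraction) && supplement_fraction >= 0 &&
        supplement_fraction <= 1, "supplement_fraction")
  chk(is.numeric(supplement_shift) && is.finite(supplement_shift),
      "supplement_shift")
  structure(list(n = as.integer(n), p_male = p_male,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_range = bmi_range,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 day_weights = day_weights, model = model,
                 supplement_fraction = supplement_fraction,
                 supplement_shift = supplement_shift, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws sex, BMI, age, and day-of-year from the spec's marginals (month
#' by weight, then uniform day within the month, non-leap calendar), then
#' sets sqrt(25(OH)D) to the model mean plus Gaussian noise of SD
#' `sigma_eps` (plus the supplementation shift for supplemented rows),
#' clamps at zero, and squares. Deterministic under a given seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; overrides `spec$seed`.
#' @return data.frame with columns `sex`, `age`, `bmi`, `day`, `vitd`,
#'   `supplemented`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  local_seed(seed)
  n <- spec$n
  sex <- ifelse(stats::runif(n) < spec$p_male, "M", "F")
  bmi <- rtruncnorm(n, spec$bmi_mean, spec$bmi_sd,
                    spec$bmi_range[1], spec$bmi_range[2])
  age <- rtruncnorm(n, spec$age_mean, spec$age_sd,
                    spec$age_range[1], spec$age_range[2])
  month <- sample.int(12L, n, replace = TRUE, prob = spec$day_weights)
  dom <- 1L + floor(stats::runif(n) * .MONTH_DAYS[month])
  day <- day_of_year(month, dom)
  supplemented <- stats::runif(n) < spec$supplement_fraction
  mu <- mean_sqrt(spec$model, sex, bmi, day)
  sq <- mu + stats::rnorm(n, 0, spec$model$sigma_eps) +
    spec$supplement_shift * supplemented
  data.frame(sex = sex, age = age, bmi = bmi, day = day,
             vitd = pmax(sq, 0)^2, supplemented = supplemented)
}

#' Simulate cohorts from a fitted model
#'
#' `simulate()` method wrapping [generate_cohort()] with the model as the
#' generating mechanism.
#'
#' @param object a [vitd_model()].
#' @param nsim number of cohorts.
#' @param seed integer seed; cohort i uses `seed + i - 1`.
#' @param n rows per cohort.
#' @param ... further arguments to [cohort_spec()].
#' @return a single cohort data.frame if `nsim = 1`, else a list of them.
#' @export
simulate.vitd_model <- function(object, nsim = 1, seed = NULL, n = 5000L,
                                ...) {
  spec <- cohort_spec(n = n, model = object, ...)
  out <- lapply(seq_len(nsim), function(i) {
    generate_cohort(spec, seed = if (is.null(seed)) NULL else seed + i - 1L)
  })
  if (nsim == 1) out[[1L]] else out
}

#' Generate paired measurements of two assay methods
#'
#' Emulates a method-comparison experiment: latent true concentrations are
#' drawn uniformly over `truth_range`; method A reads truth plus noise,
#' method B reads `intercept + slope * truth` plus noise.
#'
#' @param n number of samples, at least 3.
#' @param line a `"pb_fit"` defining the systematic between-method
#'   relation (default: the bundled published line).
#' @param noise_sd measurement noise SD on each axis; nonnegative.
#' @param seed integer seed.
#' @param truth_range range of latent concentrations (nmol/L).
#' @return data.frame with `sample_id`, `method_a`, `method_b`.
#' @export
generate_paired_measurements <- function(n, line = published_calibration(),
                                         noise_sd = 4, seed = NULL,
                                         truth_range = c(15, 120)) {
  if (n < 3L) stop("'n' must be at least 3", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be nonnegative", call. = FALSE)
  }
  stopifnot(inherits(line, "pb_fit"))
  local_seed(seed)
  truth <- stats::runif(n, truth_range[1], truth_range[2])
  data.frame(sample_id = seq_len(n),
             method_a = truth + stats::rnorm(n, 0, noise_sd),
             method_b = line$intercept + line$slope * truth +
               stats::rnorm(n, 0, noise_sd))
}
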