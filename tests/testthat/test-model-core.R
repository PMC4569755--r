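# Closed-form prediction math: fitted means, centiles, inverse quantiles,
# seasonal extrema, and the coefficient-file format.

ref_model <- published_vitd_model()

test_that("model constructor enforces its invariants", {
  expect_error(vitd_model(1:9, 1), "10")
  expect_error(vitd_model(rep(0, 10), 0), "positive")
  expect_error(vitd_model(rep(0, 10), -1), "positive")
  m <- vitd_model(published_beta, 1.36, "published-2015")
  expect_s3_class(m, "vitd_model")
  expect_identical(unname(coef(m)), published_beta)
})

test_that("mean_sqrt agrees with a term-by-term oracle to 1e-12", {
  set.seed(42)
  for (i in 1:50) {
    sex <- sample(c("M", "F"), 1)
    bmi <- runif(1, 18, 40)
    day <- sample(365, 1)
    expect_equal(mean_sqrt(ref_model, sex, bmi, day),
                 oracle_mean_sqrt(published_beta, sex, bmi, day),
                 tolerance = 1e-12)
  }
  expect_equal(mean_sqrt(ref_model, "F", 20, 234), 8.315, tolerance = 1e-3)
  expect_equal(mean_sqrt(ref_model, "M", 25, 1), 6.107, tolerance = 1e-3)
  zero <- vitd_model(rep(0, 10), 1)
  expect_identical(mean_sqrt(zero, "F", 31.7, 123), 0)
})

test_that("median centiles reproduce the reference worked examples", {
  expect_equal(round(vitd_centile(ref_model, "F", 20, 234, 0.5), 1), 69.1)
  q <- vitd_quantile(ref_model, "M", 25, 1, 60)
  expect_equal(round(100 * q, 1), 88.6)
  # the centile at that quantile returns the measurement
  expect_equal(vitd_centile(ref_model, "M", 25, 1, q), 60, tolerance = 1e-9)
})

test_that("centile is nondecreasing in alpha and equals the squared mean at 0.5", {
  alphas <- seq(0.01, 0.99, by = 0.01)
  for (case in list(c("M", 22, 15), c("F", 20, 234), c("M", 39, 300),
                    c("F", 33, 70))) {
    cs <- vitd_centile(ref_model, case[1], as.numeric(case[2]),
                       as.numeric(case[3]), alphas)
    expect_true(all(diff(cs) >= 0))
    expect_equal(vitd_centile(ref_model, case[1], as.numeric(case[2]),
                              as.numeric(case[3]), 0.5),
                 mean_sqrt(ref_model, case[1], as.numeric(case[2]),
                           as.numeric(case[3]))^2, tolerance = 1e-12)
  }
})

test_that("quantile_of inverts centile and is increasing in the value", {
  for (a in c(0.05, 0.3, 0.5, 0.9, 0.99)) {
    v <- vitd_centile(ref_model, "F", 30, 100, a)
    expect_equal(vitd_quantile(ref_model, "F", 30, 100, v), a,
                 tolerance = 1e-9)
  }
  q <- vitd_quantile(ref_model, "M", 27, 200, c(10, 30, 50, 80, 120))
  expect_true(all(diff(q) > 0))
})

test_that("alpha and value domain errors are raised, percent alpha rejected", {
  expect_error(vitd_centile(ref_model, "M", 25, 1, 0), "between 0 and 1")
  expect_error(vitd_centile(ref_model, "M", 25, 1, 1), "between 0 and 1")
  expect_error(vitd_centile(ref_model, "M", 25, 1, 50), "between 0 and 1")
  expect_error(vitd_quantile(ref_model, "M", 25, 1, -5), "nonnegative")
})

test_that("negative pre-square centiles clamp to zero with a warning", {
  # extreme low alpha at high BMI drives the sqrt-scale centile negative
  expect_warning(v <- vitd_centile(ref_model, "M", 40, 70, 1e-6),
                 "clamped")
  expect_identical(v, 0)
  # clamping preserves monotonicity through the clamp point
  suppressWarnings({
    cs <- vitd_centile(ref_model, "M", 40, 70, c(1e-7, 1e-6, 1e-3, 0.5))
  })
  expect_true(all(diff(cs) >= 0))
})

test_that("seasonal extrema match the reported calendar dates", {
  expect_identical(unname(extremum_days(ref_model, "M")), c(70L, 234L))
  expect_identical(unname(extremum_days(ref_model, "F")), c(77L, 234L))
  # BMI-invariance: the seasonal profile is additive in the BMI terms
  for (b in c(19, 25, 39)) {
    expect_identical(extremum_days(ref_model, "M", b),
                     extremum_days(ref_model, "M"))
  }
  # the shared maximum date is confirmed, not assumed
  expect_identical(extremum_days(ref_model, "M")[["day_max"]],
                   extremum_days(ref_model, "F")[["day_max"]])
  # constant seasonal profile: tie broken at the smallest index
  flat <- vitd_model(c(5, 0, 0, 0, 0, -81.08, -165.6, -1174, 0, 0), 1.36)
  expect_identical(unname(extremum_days(flat, "M")), c(1L, 1L))
})

test_that("amplitude-phase reparameterisation leaves the mean unchanged", {
  b1 <- published_beta[2]; b2 <- published_beta[3]
  amp <- sqrt(b1^2 + b2^2); phase <- atan2(b2, b1)
  a <- 2 * pi * (1:365 - 1) / 365
  expect_equal(b1 * sin(a) + b2 * cos(a), amp * sin(a + phase),
               tolerance = 1e-12)
})

test_that("model files round-trip bit-exactly and canonically", {
  f <- withr::local_tempfile(fileext = ".json")
  write_vitd_model(ref_model, f)
  back <- read_vitd_model(f)
  expect_identical(back$beta, ref_model$beta)
  expect_identical(back$sigma_eps, ref_model$sigma_eps)
  expect_identical(back$provenance, ref_model$provenance)
  # write(read(f)) is byte-identical for a canonical file
  f2 <- withr::local_tempfile(fileext = ".json")
  write_vitd_model(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # awkward coefficients survive at full double precision
  odd <- vitd_model(c(pi, -exp(1), 1/3, published_beta[4:10]), sqrt(2))
  write_vitd_model(odd, f)
  expect_identical(read_vitd_model(f)$beta, odd$beta)
  # malformed files are rejected
  writeLines('{"beta0": 1}', f)
  expect_error(read_vitd_model(f), "beta0..beta9")
})

test_that("predict method dispatches on type and accepts ISO dates", {
  nd <- data.frame(sex = c("F", "M"), bmi = c(20, 25),
                   date = c("2005-08-22", "2005-01-01"), vitd = c(69.1, 60))
  expect_equal(round(predict(ref_model, nd)[1], 1), 69.1)
  expect_equal(round(predict(ref_model, nd, type = "quantile")[2], 3), 0.886)
  expect_equal(predict(ref_model, nd, type = "sqrt"),
               mean_sqrt(ref_model, nd$sex, nd$bmi, c(234, 1)))
  expect_error(predict(ref_model, data.frame(sex = "F", bmi = 20)),
               "'day' or 'date'")
})
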