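# Refitting on cohorts: OLS on the sqrt scale, BIC, candidate selection.

ref_model <- published_vitd_model()

noiseless_cohort <- function(n = 400, seed = 11) {
  spec <- cohort_spec(n = n, model = vitd_model(coef(ref_model), 1e-12),
                      supplement_fraction = 0)
  co <- generate_cohort(spec, seed = seed)
  co$vitd <- mean_sqrt(ref_model, co$sex, co$bmi, co$day)^2  # exact medians
  co
}

test_that("a noiseless cohort is interpolated exactly", {
  co <- noiseless_cohort()
  fit <- vitd_fit(co)
  expect_equal(unname(coef(fit)), unname(coef(ref_model)), tolerance = 1e-8)
  expect_lt(fit$rss, 1e-14)
  expect_identical(fit$n, 400L)
  expect_identical(fit$k, 10L)
})

test_that("coefficients match an independent normal-equation solve", {
  co <- generate_cohort(cohort_spec(n = 800, supplement_fraction = 0),
                        seed = 5)
  fit <- vitd_fit(co)
  X <- design_vector(co$sex, co$bmi, co$day)
  expect_equal(unname(coef(fit)), unname(oracle_ols(X, sqrt(co$vitd))),
               tolerance = 1e-8)
  # unbiased residual-variance denominator (n - k)
  expect_equal(fit$sigma_eps, sqrt(fit$rss / (fit$n - fit$k)),
               tolerance = 1e-12)
  # residuals orthogonal to every standardized design column
  Z <- scale(X[, -1]); dots <- crossprod(Z, residuals(fit)) / fit$n
  expect_lt(max(abs(dots)), 1e-6)
})

test_that("degenerate and malformed cohorts are rejected informatively", {
  co <- noiseless_cohort(n = 10)
  expect_error(vitd_fit(co[1:10, ]), "more rows")
  co2 <- noiseless_cohort(n = 50)
  co2$vitd[c(3, 7)] <- NA
  expect_error(vitd_fit(co2), "rows: 3, 7")
  expect_error(vitd_fit(data.frame(sex = "M", bmi = 25, day = 1)), "'vitd'")
  # single-sex cohort: the female-harmonic columns duplicate the harmonics
  cof <- noiseless_cohort(n = 200)
  cof <- cof[cof$sex == "F", ]
  expect_error(vitd_fit(cof), "collinear.*f_sin1|collinear.*f_cos1")
})

test_that("fits embed into the prediction layout and reproduce their medians", {
  co <- generate_cohort(cohort_spec(n = 600, supplement_fraction = 0),
                        seed = 9)
  fit <- vitd_fit(co)
  m <- as_vitd_model(fit, provenance = "refit-test")
  expect_equal(vitd_centile(m, co$sex, co$bmi, co$day, 0.5),
               fitted(fit)^2, tolerance = 1e-10)
  # candidates outside the layout cannot be embedded
  fit_age <- vitd_fit(co, c(reference_terms(), "age"))
  expect_error(as_vitd_model(fit_age), "cannot embed")
})

test_that("BIC follows the profile-likelihood form and its shift laws", {
  co <- generate_cohort(cohort_spec(n = 500, supplement_fraction = 0),
                        seed = 13)
  fit <- vitd_fit(co)
  expect_equal(vitd_bic(fit),
               fit$n * log(fit$rss / fit$n) + (fit$k + 1) * log(fit$n),
               tolerance = 1e-12)
  # nested model has larger rss
  sub <- vitd_fit(co, setdiff(reference_terms(), "harmonic2"))
  expect_gt(sub$rss, fit$rss)
  # doubling every residual shifts BIC by n*log(4) at fixed k; the added
  # constant only moves the intercept and keeps the sqrt response positive
  co2 <- co
  co2$vitd <- (fitted(fit) + 2 * residuals(fit) + 5)^2
  fit2 <- vitd_fit(co2)
  expect_equal(vitd_bic(fit2) - vitd_bic(fit), fit$n * log(4),
               tolerance = 1e-6)
  # an exact interpolation has no finite BIC
  fit0 <- fit
  fit0$rss <- 0
  expect_error(vitd_bic(fit0), "RSS is zero")
})

test_that("BIC selection discards a null age term and keeps a real one", {
  spec <- cohort_spec(n = 5000, supplement_fraction = 0)
  cands <- list(reference = reference_terms(), with_age = c(reference_terms(), "age"))
  hits_null <- 0L
  for (s in 1:20) {
    co <- generate_cohort(spec, seed = 100 + s)
    sel <- vitd_select(co, cands)
    hits_null <- hits_null + (sel$table$candidate[sel$table$selected] ==
                                "reference")
  }
  expect_gte(hits_null, 15L)  # age is truly null in the generator
  # inject a strong age effect: the age-containing candidate must win
  co <- generate_cohort(spec, seed = 321)
  co$vitd <- (sqrt(co$vitd) + 0.1 * (co$age - 50))^2
  sel <- vitd_select(co, cands)
  expect_identical(sel$table$candidate[sel$table$selected], "with_age")
})

test_that("selection handles single candidates, ties, and failures", {
  co <- generate_cohort(cohort_spec(n = 300, supplement_fraction = 0),
                        seed = 2)
  sel1 <- vitd_select(co, list(only = reference_terms()))
  expect_identical(sel1$table$candidate[sel1$table$selected], "only")
  # identical candidates: first wins by order
  sel2 <- vitd_select(co, list(a = reference_terms(), b = reference_terms()))
  expect_identical(sel2$table$candidate[sel2$table$selected], "a")
  # unfittable candidates are skipped, not fatal
  cof <- co[co$sex == "F", ]
  sel3 <- vitd_select(cof, list(
    bad = reference_terms(),
    ok = setdiff(reference_terms(), c("sex_harmonic1", "male_lowbmi_spline"))))
  expect_identical(sel3$table$candidate[sel3$table$selected], "ok")
  expect_true(is.na(sel3$table$bic[1]))
  # a BIC table can be exported
  f <- withr::local_tempfile(fileext = ".csv")
  write_bic_table(sel3, f)
  expect_identical(nrow(utils::read.csv(f)), 2L)
})

test_that("sigma_eps estimates concentrate around the generating value", {
  spec <- cohort_spec(n = 5000, supplement_fraction = 0)
  sigmas <- vapply(1:25, function(s) {
    vitd_fit(generate_cohort(spec, seed = 500 + s))$sigma_eps
  }, numeric(1))
  expect_gte(mean(sigmas >= 1.30 & sigmas <= 1.42), 0.95)
})
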