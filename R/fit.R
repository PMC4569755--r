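# Refitting the seasonal model on a cohort and BIC-based candidate choice.
#
# Fits are ordinary least squares on sqrt(25(OH)D). Candidate models are
# named subsets of a fixed term registry; the intercept is always included.

.TERM_REGISTRY <- c("harmonic1", "harmonic2", "tbmi", "tbmi2",
                    "male_lowbmi_spline", "sex_harmonic1",
                    "sex", "age", "age_sex", "age_tbmi")

#' Term set of the reference model
#'
#' The terms whose design columns reproduce the published ten-coefficient
#' layout: both harmonic pairs, the transformed BMI and its square, the
#' male low-BMI spline, and the female-by-annual-harmonic interaction.
#'
#' @return character vector of term identifiers.
#' @export
reference_terms <- function() {
  c("harmonic1", "harmonic2", "tbmi", "tbmi2",
    "male_lowbmi_spline", "sex_harmonic1")
}

#' Default candidate models for BIC selection
#'
#' Covers the determinants named in the study design — seasonal harmonics
#' (one vs two pairs), BMI terms, sex main effect and sex interactions,
#' and age main/interaction effects — without claiming to replicate any
#' particular historical search.
#'
#' @return named list of character term vectors.
#' @export
default_candidates <- function() {
  ref <- reference_terms()
  list(
    reference          = ref,
    reference_age      = c(ref, "age"),
    reference_sex      = c(ref, "sex"),
    reference_age_sex  = c(ref, "sex", "age", "age_sex"),
    one_harmonic       = setdiff(ref, "harmonic2"),
    no_sex_season      = c(setdiff(ref, "sex_harmonic1"), "sex"),
    no_bmi_spline      = setdiff(ref, "male_lowbmi_spline"),
    bmi_linear         = c("harmonic1", "harmonic2", "tbmi", "sex_harmonic1")
  )
}

# Resolve the day column (integer `day` or ISO `date`) of a cohort table.
cohort_day <- function(cohort) {
  if ("day" %in% names(cohort)) resolve_day(cohort$day)
  else if ("date" %in% names(cohort)) resolve_day(cohort$date)
  else stop("cohort needs a 'day' or 'date' column", call. = FALSE)
}

# Design columns for one term identifier.
term_columns <- function(term, sex, bmi, day, age) {
  sb <- seasonal_basis(day)
  tb <- bmi_transform(bmi)
  female <- as.numeric(sex == "F")
  need_age <- function() {
    if (is.null(age) || anyNA(age)) {
      stop("term '", term, "' needs a complete 'age' column", call. = FALSE)
    }
    age
  }
  switch(term,
    harmonic1 = cbind(sin1 = sb[, "s1"], cos1 = sb[, "c1"]),
    harmonic2 = cbind(sin2 = sb[, "s2"], cos2 = sb[, "c2"]),
    tbmi  = cbind(tbmi = tb),
    tbmi2 = cbind(tbmi2 = tb^2),
    male_lowbmi_spline =
      cbind(male_lowbmi = (1 - female) * (bmi < 25) *
              (tb - bmi_transform(25))^2),
    sex_harmonic1 = cbind(f_sin1 = female * sb[, "s1"],
                          f_cos1 = female * sb[, "c1"]),
    sex = cbind(female = female),
    age = cbind(age = need_age()),
    age_sex = cbind(age_female = need_age() * female),
    age_tbmi = cbind(age_tbmi = need_age() * tb),
    stop("unknown term '", term, "'; known terms: ",
         paste(.TERM_REGISTRY, collapse = ", "), call. = FALSE)
  )
}

# Full design matrix for a candidate term set (intercept first).
candidate_design <- function(cohort, terms) {
  terms <- unique(setdiff(terms, "intercept"))
  bad <- setdiff(terms, .TERM_REGISTRY)
  if (length(bad)) {
    stop("unknown term(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  terms <- .TERM_REGISTRY[.TERM_REGISTRY %in% terms]  # canonical order
  sex <- .check_sex(cohort$sex, nrow(cohort))
  day <- cohort_day(cohort)
  cols <- lapply(terms, term_columns, sex = sex, bmi = cohort$bmi,
                 day = day, age = cohort$age)
  X <- do.call(cbind, c(list(`(Intercept)` = rep(1, nrow(cohort))), cols))
  colnames(X)[1] <- "(Intercept)"
  X
}

#' Fit the seasonal 25(OH)D regression on a cohort
#'
#' Ordinary least squares on square-root transformed 25(OH)D for a chosen
#' candidate term set. The residual SD uses the unbiased denominator
#' (n - k) with k the number of regression coefficients. Rows with missing
#' covariates are dropped listwise with a message; rows with missing
#' outcome are an error (the caller must decide what they mean).
#'
#' @param cohort data.frame with columns `sex`, `bmi`, `day` (or `date`),
#'   `vitd` (nmol/L), and `age` when an age term is requested.
#' @param terms character vector of term identifiers (see
#'   [reference_terms()], [default_candidates()]); the intercept is implicit.
#' @return an object of class `"vitd_fit"` with components `coefficients`,
#'   `se`, `sigma_eps`, `n`, `k`, `rss`, `r_squared`, `bic`, `term_labels`
#'   and, when the candidate nests inside the reference layout, `model`
#'   (a [vitd_model()] with absent terms set to zero).
#' @examples
#' spec <- cohort_spec(n = 400)
#' fit <- vitd_fit(generate_cohort(spec, seed = 1))
#' summary(fit)
#' @export
vitd_fit <- function(cohort, terms = reference_terms()) {
  cohort <- as.data.frame(cohort)
  if (is.null(cohort$vitd)) stop("cohort has no 'vitd' column", call. = FALSE)
  if (anyNA(cohort$vitd)) {
    stop("missing 'vitd' in rows: ",
         paste(utils::head(which(is.na(cohort$vitd)), 10L), collapse = ", "),
         call. = FALSE)
  }
  if (any(cohort$vitd < 0)) stop("'vitd' must be nonnegative", call. = FALSE)
  used <- intersect(c("sex", "bmi", "day", "date",
                      if (any(grepl("age", terms))) "age"), names(cohort))
  complete <- stats::complete.cases(cohort[used])
  if (!all(complete)) {
    message("dropping ", sum(!complete), " row(s) with missing covariates")
    cohort <- cohort[complete, , drop = FALSE]
  }

  X <- candidate_design(cohort, terms)
  y <- sqrt(cohort$vitd)
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("need more rows (", n, ") than coefficients (", k, ")",
                   call. = FALSE)
  qx <- qr(X)
  if (qx$rank < k) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):k]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  sigma <- sqrt(rss / (n - k))
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(diag(xtx_inv)) * sigma
  names(se) <- colnames(X)
  tss <- sum((y - mean(y))^2)

  term_labels <- colnames(X)
  model <- NULL
  if (all(term_labels %in% model_term_names())) {
    full <- stats::setNames(numeric(10L), model_term_names())
    full[term_labels] <- beta
    model <- vitd_model(full, sigma,
                        provenance = paste0("refit-", format(Sys.Date())))
  }
  structure(list(coefficients = beta, se = se, sigma_eps = sigma,
                 n = n, k = k, rss = rss,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 bic = if (rss > 0) n * log(rss / n) + (k + 1) * log(n)
                       else NA_real_,
                 term_labels = term_labels,
                 terms = unique(setdiff(terms, "intercept")),
                 model = model,
                 fitted = y - res, residuals = res),
            class = "vitd_fit")
}

#' Bayesian information criterion of a fit
#'
#' Gaussian profile-likelihood convention up to constants:
#' n * log(RSS / n) + k * log(n), with k counting the regression
#' coefficients plus the residual-variance parameter. Only differences
#' between candidates fitted to the same data are meaningful.
#'
#' @param fit a [vitd_fit()] result.
#' @return a single number; lower is better.
#' @export
vitd_bic <- function(fit) {
  stopifnot(inherits(fit, "vitd_fit"))
  if (fit$rss <= 0) {
    stop("RSS is zero: BIC degenerates to -Inf for an interpolating fit",
         call. = FALSE)
  }
  fit$n * log(fit$rss / fit$n) + (fit$k + 1) * log(fit$n)
}

#' Select the best candidate model by BIC
#'
#' Fits every candidate on the same cohort and returns the one with the
#' smallest BIC, along with the full comparison table. Ties (and exact
#' equality) are broken by candidate order. Candidates that cannot be
#' fitted (e.g. rank-deficient on a single-sex cohort) are recorded with
#' `NA` and skipped.
#'
#' @param cohort as in [vitd_fit()].
#' @param candidates named list of term vectors; default
#'   [default_candidates()].
#' @return an object of class `"vitd_select"`: list with `best` (the
#'   winning `"vitd_fit"`), `table` (data.frame: candidate, k, rss,
#'   r_squared, bic, selected), and `fits`.
#' @export
vitd_select <- function(cohort, candidates = default_candidates()) {
  if (!length(candidates)) stop("no candidates supplied", call. = FALSE)
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("candidate", seq_along(candidates))
  }
  fits <- lapply(candidates, function(tm) {
    tryCatch(vitd_fit(cohort, tm), error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) {
    stop("no candidate could be fitted; first error: ",
         conditionMessage(fits[[1L]]), call. = FALSE)
  }
  bics <- ifelse(ok, vapply(fits, function(f)
    if (inherits(f, "vitd_fit")) f$bic else NA_real_, numeric(1)), NA_real_)
  best <- which.min(bics)  # first minimum: deterministic tie-break
  tab <- data.frame(
    candidate = names(candidates),
    k = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "vitd_fit")) f$k else NA_integer_, numeric(1)), NA),
    rss = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "vitd_fit")) f$rss else NA_real_, numeric(1)), NA),
    r_squared = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "vitd_fit")) f$r_squared else NA_real_, numeric(1)), NA),
    bic = bics,
    selected = seq_along(fits) == best,
    row.names = NULL)
  structure(list(best = fits[[best]], table = tab,
                 fits = fits[ok]), class = "vitd_select")
}

#' Write a BIC comparison table to CSV
#'
#' @param selection a [vitd_select()] result.
#' @param path output file.
#' @export
write_bic_table <- function(selection, path) {
  stopifnot(inherits(selection, "vitd_select"))
  utils::write.csv(selection$table, path, row.names = FALSE)
  invisible(path)
}

#' Extract the coefficient set of a fit as a prediction-ready model
#'
#' Embeds the fitted coefficients into the fixed ten-term layout (absent
#' terms zero). Only candidates whose terms nest inside the reference
#' layout can be embedded; fits with age or sex main-effect terms cannot.
#'
#' @param fit a [vitd_fit()].
#' @param provenance optional provenance label.
#' @return a [vitd_model()].
#' @export
as_vitd_model <- function(fit, provenance = NULL) {
  stopifnot(inherits(fit, "vitd_fit"))
  if (is.null(fit$model)) {
    stop("fit contains terms outside the reference layout (",
         paste(setdiff(fit$term_labels, model_term_names()), collapse = ", "),
         "); cannot embed", call. = FALSE)
  }
  m <- fit$model
  if (!is.null(provenance)) m$provenance <- provenance
  m
}

#' @export
print.vitd_fit <- function(x, ...) {
  cat("Seasonal 25(OH)D regression fit (sqrt scale)\n")
  cat("  n =", x$n, " terms:", paste(x$terms, collapse = " + "), "\n")
  cat("  sigma_eps =", format(x$sigma_eps, digits = 4),
      " R^2 =", format(x$r_squared, digits = 3),
      " BIC =", format(x$bic, digits = 6), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
summary.vitd_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = z,
               `Pr(>|t|)` = 2 * stats::pt(-abs(z), object$n - object$k))
  structure(list(coefficients = tab, sigma_eps = object$sigma_eps,
                 n = object$n, k = object$k, r_squared = object$r_squared,
                 bic = object$bic), class = "summary.vitd_fit")
}

#' @export
print.summary.vitd_fit <- function(x, ...) {
  cat("Seasonal 25(OH)D regression: n =", x$n, ", k =", x$k, "\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat("Residual SD:", format(x$sigma_eps, digits = 4),
      " R^2:", format(x$r_squared, digits = 3),
      " BIC:", format(x$bic, digits = 6), "\n")
  invisible(x)
}

#' @export
coef.vitd_fit <- function(object, ...) object$coefficients

#' @export
residuals.vitd_fit <- function(object, ...) object$residuals

#' @export
fitted.vitd_fit <- function(object, ...) object$fitted

#' @export
predict.vitd_fit <- function(object, newdata, ...) {
  predict(as_vitd_model(object), newdata, ...)
}

#' @export
print.vitd_select <- function(x, ...) {
  cat("BIC model selection over", nrow(x$table), "candidates\n")
  print(x$table, digits = 6)
  invisible(x)
}
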