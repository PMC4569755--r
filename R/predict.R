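# Closed-form prediction on the sqrt scale and back-transformed centiles.
#
# On the transformed scale the model is homoscedastic Gaussian, so the
# alpha centile is yhat + z_alpha * sigma_eps; squaring returns nmol/L.

#' Fitted mean on the square-root scale
#'
#' Inner product of the model coefficients with the design vector for one
#' or more covariate combinations.
#'
#' @param model a [vitd_model()].
#' @param sex "M" or "F" (vectorised, recycled).
#' @param bmi BMI in kg/m^2.
#' @param day day-of-year index 1..365.
#' @return numeric vector of fitted values in sqrt(nmol/L).
#' @export
mean_sqrt <- function(model, sex, bmi, day) {
  stopifnot(inherits(model, "vitd_model"))
  as.vector(design_vector(sex, bmi, day) %*% model$beta)
}

#' Centile of the 25(OH)D distribution
#'
#' The alpha centile on the original scale is (yhat + z_alpha * sigma_eps)^2
#' where yhat is the fitted sqrt-scale mean and z_alpha the standard normal
#' alpha quantile. A negative pre-square value (possible only at extreme
#' alpha) is clamped at zero with a warning, which preserves monotonicity
#' in alpha; squaring a negative value would silently break it.
#'
#' @inheritParams mean_sqrt
#' @param alpha probability in (0, 1); `alpha = 0.5` gives the median.
#'   Percent-scale inputs (>= 1) are rejected, not rescaled.
#' @return centile values in nmol/L.
#' @examples
#' vitd_centile(published_vitd_model(), "F", 20, day_of_year(8, 22), 0.5)
#' @export
vitd_centile <- function(model, sex, bmi, day, alpha = 0.5) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
      any(alpha <= 0) || any(alpha >= 1)) {
    stop("'alpha' must be a probability strictly between 0 and 1",
         call. = FALSE)
  }
  pre <- mean_sqrt(model, sex, bmi, day) + stats::qnorm(alpha) * model$sigma_eps
  if (any(pre < 0)) {
    warning("centile clamped at 0 nmol/L for ", sum(pre < 0),
            " combination(s); requested alpha is below the model support",
            call. = FALSE)
    pre <- pmax(pre, 0)
  }
  pre^2
}

#' Population quantile of a measured 25(OH)D value
#'
#' Inverts a measurement into the fraction of the reference population
#' expected to lie below it on that date: Phi((sqrt(value) - yhat) /
#' sigma_eps). Exact inverse of [vitd_centile()] wherever no clamping
#' occurred.
#'
#' @inheritParams mean_sqrt
#' @param value measured 25(OH)D in nmol/L; must be nonnegative.
#' @return probabilities in (0, 1).
#' @examples
#' vitd_quantile(published_vitd_model(), "M", 25, 1, 60)  # ~0.886
#' @export
vitd_quantile <- function(model, sex, bmi, day, value) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0)) {
    stop("'value' must be a nonnegative 25(OH)D level in nmol/L",
         call. = FALSE)
  }
  yhat <- mean_sqrt(model, sex, bmi, day)
  stats::pnorm((sqrt(value) - yhat) / model$sigma_eps)
}

#' Days of seasonal minimum and maximum
#'
#' Argmin and argmax of the predicted sqrt-scale mean over integer days
#' 1..365. BMI terms are constant in day, so the result does not depend on
#' BMI; ties are broken by the smallest day index.
#'
#' @inheritParams mean_sqrt
#' @param bmi BMI used for evaluation (result is BMI-invariant).
#' @return named integer vector `c(day_min, day_max)`.
#' @export
extremum_days <- function(model, sex, bmi = 25) {
  mu <- mean_sqrt(model, sex, bmi, 1:365)
  c(day_min = which.min(mu), day_max = which.max(mu))
}

#' Predict centiles or quantiles from a seasonal 25(OH)D model
#'
#' @param object a [vitd_model()].
#' @param newdata data.frame with columns `sex`, `bmi`, and either `day`
#'   (integer 1..365) or `date` (ISO-8601 / Date); for `type = "quantile"`
#'   also `vitd` (nmol/L).
#' @param type `"centile"` (default; nmol/L at probability `alpha`),
#'   `"sqrt"` (fitted mean on the sqrt scale), or `"quantile"`
#'   (population quantile of the `vitd` column).
#' @param alpha centile probability, used when `type = "centile"`.
#' @param ... unused.
#' @return numeric vector, one value per row of `newdata`.
#' @examples
#' m <- published_vitd_model()
#' predict(m, data.frame(sex = "F", bmi = 20, date = "2005-08-22"))
#' predict(m, data.frame(sex = "M", bmi = 25, day = 1, vitd = 60),
#'         type = "quantile")
#' @export
predict.vitd_model <- function(object, newdata,
                               type = c("centile", "sqrt", "quantile"),
                               alpha = 0.5, ...) {
  type <- match.arg(type)
  nd <- as.data.frame(newdata)
  day <- if ("day" %in% names(nd)) resolve_day(nd$day)
         else if ("date" %in% names(nd)) resolve_day(nd$date)
         else stop("'newdata' needs a 'day' or 'date' column", call. = FALSE)
  switch(type,
    centile  = vitd_centile(object, nd$sex, nd$bmi, day, alpha),
    sqrt     = mean_sqrt(object, nd$sex, nd$bmi, day),
    quantile = {
      if (is.null(nd$vitd)) stop("type = \"quantile\" needs a 'vitd' column",
                                 call. = FALSE)
      vitd_quantile(object, nd$sex, nd$bmi, day, nd$vitd)
    })
}

#' Plot seasonal centile curves
#'
#' Draws centile curves of 25(OH)D against day of year for one sex and a
#' set of BMI values, in the style of reference growth charts.
#'
#' @param x a [vitd_model()].
#' @param sex "M" or "F".
#' @param bmi BMI values, one panel line group per value.
#' @param alpha centile probabilities to draw.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the matrix of plotted centiles (days x curves).
#' @export
plot.vitd_model <- function(x, sex = "M", bmi = 25,
                            alpha = c(0.05, 0.25, 0.5, 0.75, 0.95), ...) {
  days <- 1:365
  grid <- expand.grid(alpha = alpha, bmi = bmi)
  curves <- mapply(function(a, b) vitd_centile(x, sex, b, days, a),
                   grid$alpha, grid$bmi)
  colnames(curves) <- sprintf("bmi%g_a%g", grid$bmi, grid$alpha)
  graphics::matplot(days, curves, type = "l", lty = 1,
                    col = rep(seq_along(bmi), each = length(alpha)),
                    xlab = "day of year", ylab = "25(OH)D [nmol/L]",
                    main = sprintf("Seasonal 25(OH)D centiles (%s)", sex), ...)
  invisible(curves)
}
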