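# Design construction for the seasonal 25(OH)D model.
#
# The linear predictor lives on the square-root scale and uses ten terms:
# intercept, an annual sine/cosine pair, a semi-annual pair, the transformed
# BMI and its square, a male-only low-BMI spline term, and a female-by-annual
# harmonic interaction. Time enters as the angle 2*pi*(day - 1)/365.

.MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.MONTH_OFFSET <- c(0L, cumsum(.MONTH_DAYS))[1:12]

#' Inverse square-root BMI transform
#'
#' Transforms body-mass index as t(x) = -1/sqrt(x). The transform is
#' strictly increasing, always negative, and damps the influence of very
#' large BMI values in the regression.
#'
#' @param bmi numeric vector of BMI values in kg/m^2; must be positive.
#' @return numeric vector, dimensionless, in (-Inf, 0).
#' @examples
#' bmi_transform(25)  # -0.2
#' @export
bmi_transform <- function(bmi) {
  if (!is.numeric(bmi) || any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("'bmi' must be finite and positive", call. = FALSE)
  }
  -1 / sqrt(bmi)
}

#' Day-of-year index of a calendar date
#'
#' Maps (month, day-of-month) to the 1..365 index used by the seasonal
#' terms. The mapping is the non-leap calendar; February 29 is accepted and
#' assigned index 60 (shared with March 1), so leap-year dates never error
#' and all dates after February use their non-leap index.
#'
#' @param month integer 1..12.
#' @param day_of_month integer day within the month.
#' @return integer vector of day-of-year indices in 1..365.
#' @examples
#' day_of_year(8, 22)  # 234
#' @export
day_of_year <- function(month, day_of_month) {
  month <- as.integer(month)
  day_of_month <- as.integer(day_of_month)
  if (any(is.na(month)) || any(month < 1L) || any(month > 12L)) {
    stop("'month' must be in 1..12", call. = FALSE)
  }
  max_day <- .MONTH_DAYS[month] + as.integer(month == 2L)  # allow Feb 29
  if (any(is.na(day_of_month)) || any(day_of_month < 1L) ||
      any(day_of_month > max_day)) {
    stop("invalid day of month for the given month", call. = FALSE)
  }
  pmin(.MONTH_OFFSET[month] + day_of_month, 365L)
}

#' Calendar date of a day-of-year index
#'
#' Inverse of [day_of_year()] on the non-leap calendar.
#'
#' @param day integer day-of-year in 1..365.
#' @return data.frame with columns `month` and `day_of_month`.
#' @export
calendar_date <- function(day) {
  day <- .check_day(day)
  month <- findInterval(day - 1L, cumsum(.MONTH_DAYS), left.open = FALSE) + 1L
  data.frame(month = month, day_of_month = day - .MONTH_OFFSET[month])
}

.check_day <- function(day) {
  d <- as.integer(day)
  if (any(is.na(d)) || any(d < 1L) || any(d > 365L) || any(d != day)) {
    stop("'day' must be an integer in 1..365", call. = FALSE)
  }
  d
}

# Accepts integer day-of-year or an ISO-8601 date string / Date object.
resolve_day <- function(x) {
  if (inherits(x, "Date")) {
    lt <- as.POSIXlt(x)
    return(day_of_year(lt$mon + 1L, lt$mday))
  }
  if (is.character(x)) {
    d <- as.Date(x, format = "%Y-%m-%d")
    if (any(is.na(d))) stop("unparseable ISO-8601 date: ", x[is.na(d)][1L],
                            call. = FALSE)
    return(resolve_day(d))
  }
  .check_day(x)
}

#' Annual and semi-annual harmonic basis
#'
#' Evaluates the four seasonal regressors at a day-of-year index:
#' sin and cos of the annual angle 2*pi*(day - 1)/365 and of twice that
#' angle. The semi-annual pair lets the time between seasonal minimum and
#' maximum differ from six months.
#'
#' @param day integer vector of day-of-year indices in 1..365.
#' @return numeric matrix with columns `s1`, `c1`, `s2`, `c2`.
#' @examples
#' seasonal_basis(1)  # (0, 1, 0, 1)
#' @export
seasonal_basis <- function(day) {
  day <- .check_day(day)
  a <- 2 * pi * (day - 1) / 365
  cbind(s1 = sin(a), c1 = cos(a), s2 = sin(2 * a), c2 = cos(2 * a))
}

.check_sex <- function(sex, n = length(sex)) {
  sex <- as.character(sex)
  sex[sex %in% c("male", "m")] <- "M"
  sex[sex %in% c("female", "f")] <- "F"
  if (any(is.na(sex)) || !all(sex %in% c("M", "F"))) {
    stop("'sex' must be \"M\" or \"F\"", call. = FALSE)
  }
  rep_len(sex, n)
}

# Labels of the ten regressors, in the fixed coefficient order of the model.
model_term_names <- function() {
  c("(Intercept)", "sin1", "cos1", "sin2", "cos2",
    "tbmi", "tbmi2", "male_lowbmi", "f_sin1", "f_cos1")
}

#' Design matrix of the published seasonal 25(OH)D model
#'
#' Builds the n x 10 regressor matrix: intercept; annual sin/cos; semi-annual
#' sin/cos; t(BMI) = -1/sqrt(BMI) and its square; the male-only low-BMI
#' spline term I(male) * I(BMI < 25) * (t(BMI) - t(25))^2; and the
#' female-by-annual harmonic interaction. The BMI < 25 indicator is strict;
#' at BMI = 25 the spline regressor is exactly zero under either convention.
#'
#' @param sex character vector, "M" or "F" (recycled).
#' @param bmi numeric vector of BMI in kg/m^2.
#' @param day integer vector of day-of-year indices in 1..365.
#' @return numeric matrix with one row per observation and the ten columns
#'   named by [model_term_names()].
#' @examples
#' design_vector("F", 20, 234)
#' @export
design_vector <- function(sex, bmi, day) {
  n <- max(length(sex), length(bmi), length(day))
  sex <- .check_sex(sex, n)
  bmi <- rep_len(bmi, n)
  day <- rep_len(day, n)
  sb <- seasonal_basis(day)
  tb <- bmi_transform(bmi)
  female <- sex == "F"
  spline <- as.numeric(!female & bmi < 25) * (tb - bmi_transform(25))^2
  X <- cbind(1, sb[, "s1"], sb[, "c1"], sb[, "s2"], sb[, "c2"],
             tb, tb^2, spline, female * sb[, "s1"], female * sb[, "c1"])
  dimnames(X) <- list(NULL, model_term_names())
  X
}
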