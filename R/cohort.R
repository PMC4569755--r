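# Cohort table I/O and inclusion filters.
#
# The on-disk dialect is a plain CSV with columns sex {M,F}, age, bmi,
# date (ISO-8601) or day (integer 1..365), vitd_nmol_l, supplemented
# {0,1,NA}. In memory the outcome column is called `vitd` and the date is
# resolved to a day-of-year index.

#' Read a cohort CSV
#'
#' @param path CSV file with columns `sex`, `age`, `bmi`, `date` or `day`,
#'   and optionally `vitd_nmol_l` (or `vitd`) and `supplemented`.
#' @return data.frame with columns `sex`, `age`, `bmi`, `day`, `vitd`
#'   (may be absent), `supplemented` (logical, may be absent).
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age", "bmi")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("cohort file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(sex = .check_sex(d$sex, nrow(d)), age = d$age,
                    bmi = d$bmi, day = cohort_day(d))
  if (!is.null(d$vitd_nmol_l)) out$vitd <- d$vitd_nmol_l
  else if (!is.null(d$vitd)) out$vitd <- d$vitd
  if (!is.null(d$supplemented)) out$supplemented <- as.logical(d$supplemented)
  out
}

#' Write a cohort CSV
#'
#' @param cohort in-memory cohort data.frame.
#' @param path output file.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(sex = cohort$sex, age = cohort$age, bmi = cohort$bmi,
                    day = cohort_day(cohort))
  if (!is.null(cohort$vitd)) out$vitd_nmol_l <- cohort$vitd
  if (!is.null(cohort$supplemented)) {
    out$supplemented <- as.integer(cohort$supplemented)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Apply the reference-population inclusion criteria
#'
#' Keeps participants aged 35 to 65 years (inclusive) with BMI between 18
#' and 40 kg/m^2 (inclusive), and — unless `keep_supplemented` — drops
#' rows flagged as taking vitamin D supplementation. Each excluded row is
#' counted once, under the first criterion it fails (age, then BMI, then
#' supplementation), so the log totals plus kept rows equal the input rows.
#'
#' @param cohort data.frame with `age` and `bmi` columns; `supplemented`
#'   optional (absent means unknown and is treated as not supplemented).
#' @param age_range,bmi_range closed inclusion intervals.
#' @param keep_supplemented if `TRUE`, supplemented participants are kept
#'   (the whole-population refit variant).
#' @return list with `cohort` (kept rows) and `log` (named integer counts
#'   of exclusions by reason).
#' @examples
#' x <- data.frame(age = c(40, 70, 50), bmi = c(24, 25, 42))
#' apply_inclusion_criteria(x)$log
#' @export
apply_inclusion_criteria <- function(cohort, age_range = c(35, 65),
                                     bmi_range = c(18, 40),
                                     keep_supplemented = FALSE) {
  cohort <- as.data.frame(cohort)
  if (is.null(cohort$age) || is.null(cohort$bmi)) {
    stop("cohort must have 'age' and 'bmi' columns", call. = FALSE)
  }
  bad_age <- cohort$age < age_range[1] | cohort$age > age_range[2]
  bad_bmi <- !bad_age & (cohort$bmi < bmi_range[1] | cohort$bmi > bmi_range[2])
  supp <- if (is.null(cohort$supplemented)) rep(FALSE, nrow(cohort))
          else cohort$supplemented %in% TRUE
  bad_supp <- !bad_age & !bad_bmi & !keep_supplemented & supp
  keep <- !(bad_age | bad_bmi | bad_supp)
  list(cohort = cohort[keep, , drop = FALSE],
       log = c(age = sum(bad_age), bmi = sum(bad_bmi),
               supplemented = sum(bad_supp)))
}
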