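#' Export a table of seasonal centile curves
#'
#' Dense evaluation of the centile surface over a grid of days, sexes,
#' BMI values and probabilities — the tabular form of the reference
#' charts (default BMI panel values 20, 25, 30).
#'
#' @param model a [vitd_model()].
#' @param sexes character vector, subset of `c("M", "F")`.
#' @param bmi_list BMI values in kg/m^2.
#' @param alpha_list centile probabilities in (0, 1).
#' @param day_step stride over days 1..365 (1 = every day).
#' @return data.frame with columns `day`, `sex`, `bmi`, `alpha`,
#'   `centile`, and attribute `provenance` naming the model; within each
#'   (day, sex, bmi) cell the centile is nondecreasing in alpha.
#' @examples
#' head(export_curves(published_vitd_model(), day_step = 73))
#' @export
export_curves <- function(model, sexes = c("M", "F"),
                          bmi_list = c(20, 25, 30),
                          alpha_list = c(0.05, 0.25, 0.5, 0.75, 0.95),
                          day_step = 1L) {
  stopifnot(inherits(model, "vitd_model"))
  if (!length(sexes) || !length(bmi_list) || !length(alpha_list)) {
    stop("grids must be nonempty", call. = FALSE)
  }
  if (day_step < 1L || day_step > 365L) {
    stop("'day_step' must be in 1..365", call. = FALSE)
  }
  grid <- expand.grid(alpha = alpha_list, day = seq(1L, 365L, by = day_step),
                      bmi = bmi_list, sex = sexes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$centile <- vitd_centile(model, grid$sex, grid$bmi, grid$day,
                               grid$alpha)
  out <- grid[c("day", "sex", "bmi", "alpha", "centile")]
  attr(out, "provenance") <- model$provenance
  out
}
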