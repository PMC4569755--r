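# Goodness-of-fit by predicted-quantile uniformity.
#
# If the model is correctly specified, Phi((sqrt(y) - yhat)/sigma_eps) is
# uniform on (0,1) across a cohort. Departures show up in the histogram,
# the ECDF against the diagonal, and the one-sample KS statistic.

#' Predicted population quantiles of a cohort
#'
#' Converts every observation to the quantile the model assigns it.
#'
#' @param model a [vitd_model()].
#' @param cohort data.frame with `sex`, `bmi`, `day` (or `date`) and
#'   `vitd` columns; missing `vitd` is an error.
#' @return numeric vector of probabilities, one per row.
#' @export
predicted_quantiles <- function(model, cohort) {
  cohort <- as.data.frame(cohort)
  if (is.null(cohort$vitd)) stop("cohort has no 'vitd' column", call. = FALSE)
  if (anyNA(cohort$vitd)) {
    stop("missing 'vitd' in rows: ",
         paste(utils::head(which(is.na(cohort$vitd)), 10L), collapse = ", "),
         call. = FALSE)
  }
  vitd_quantile(model, cohort$sex, cohort$bmi, cohort_day(cohort),
                cohort$vitd)
}

#' One-sample Kolmogorov-Smirnov statistic against uniformity
#'
#' sup_t |ECDF(t) - t| via the order-statistic formula
#' max_i max(i/n - u_(i), u_(i) - (i-1)/n).
#'
#' @param quantiles values strictly inside (0, 1).
#' @return the KS statistic, a number in `[0, 1]`.
#' @examples
#' ks_uniform((1:10 - 0.5) / 10)  # 0.05
#' @export
ks_uniform <- function(quantiles) {
  u <- as.numeric(quantiles)
  n <- length(u)
  if (n < 1L || anyNA(u)) stop("need at least one non-missing quantile",
                               call. = FALSE)
  if (any(u <= 0 | u >= 1)) {
    stop("quantiles must lie strictly inside (0, 1)", call. = FALSE)
  }
  u <- sort(u)
  i <- seq_len(n)
  max(i / n - u, u - (i - 1) / n)
}

#' Bootstrap percentile CI for the KS statistic
#'
#' Nonparametric bootstrap: the cohort's quantiles are resampled with
#' replacement B times, the KS statistic recomputed on each resample, and
#' the percentile interval reported. Seeded and reproducible; the caller's
#' RNG stream is left untouched.
#'
#' @param quantiles as in [ks_uniform()]; length >= 2.
#' @param B number of bootstrap replicates, at least 100.
#' @param seed integer seed (default 1).
#' @param conf.level interval level (default 0.95).
#' @return numeric vector `c(lo, hi)`.
#' @export
bootstrap_ks_ci <- function(quantiles, B = 1000L, seed = 1L,
                            conf.level = 0.95) {
  n <- length(quantiles)
  if (n < 2L) stop("need at least 2 quantiles", call. = FALSE)
  if (B < 100L) stop("'B' must be at least 100", call. = FALSE)
  local_seed(seed)
  stats_b <- vapply(seq_len(B), function(b) {
    ks_uniform(quantiles[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  a <- (1 - conf.level) / 2
  unname(stats::quantile(stats_b, c(a, 1 - a)))
}

#' Observed fraction below each nominal centile
#'
#' For each alpha, the fraction of predicted quantiles strictly below it.
#' Under a correct model this tracks alpha itself (e.g. about 10% of a
#' cohort should fall under its 10% centile).
#'
#' @param quantiles probabilities in (0, 1).
#' @param alpha_list nominal centiles in (0, 1); may be empty.
#' @return data.frame with columns `alpha` and `observed`.
#' @export
proportion_below <- function(quantiles, alpha_list = c(0.03, 0.10)) {
  if (length(alpha_list) &&
      (any(alpha_list <= 0) || any(alpha_list >= 1))) {
    stop("'alpha_list' entries must be in (0, 1)", call. = FALSE)
  }
  data.frame(alpha = as.numeric(alpha_list),
             observed = vapply(alpha_list,
                               function(a) mean(quantiles < a), numeric(1)))
}

#' Validate a model against a cohort by quantile uniformity
#'
#' Composes the replication pipeline: optionally recalibrate the cohort's
#' measurements across assays, convert each observation to its predicted
#' quantile, and summarise uniformity (KS statistic with bootstrap CI,
#' histogram bin counts, observed fractions below nominal centiles).
#' With a sqrt-scale calibration line the 25(OH)D values are square-root
#' transformed, mapped through the line, and squared back before scoring.
#'
#' @param model a [vitd_model()].
#' @param cohort data.frame with `sex`, `bmi`, `day`/`date`, `vitd`.
#' @param calibration optional `"pb_fit"` line mapping the cohort's assay
#'   (method A) onto the model's assay (method B).
#' @param B bootstrap replicates for the KS interval.
#' @param seed bootstrap seed.
#' @param bins histogram bin count over `[0, 1]` (default 20).
#' @param alpha_list nominal centiles for [proportion_below()].
#' @return an object of class `"vitd_validation"`: `quantiles`, `ks_stat`,
#'   `ks_ci`, `bin_counts`, `prop_below`, `n`.
#' @export
vitd_validate <- function(model, cohort, calibration = NULL,
                          B = 1000L, seed = 1L, bins = 20L,
                          alpha_list = c(0.03, 0.10)) {
  cohort <- as.data.frame(cohort)
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "pb_fit"))
    cohort$vitd <- if (calibration$scale == "sqrt") {
      pb_apply(calibration, sqrt(cohort$vitd), "a_to_b", scale = "sqrt")^2
    } else {
      pb_apply(calibration, cohort$vitd, "a_to_b", scale = "original")
    }
    if (any(cohort$vitd < 0)) cohort$vitd <- pmax(cohort$vitd, 0)
  }
  q <- predicted_quantiles(model, cohort)
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- as.integer(table(cut(q, breaks, include.lowest = TRUE)))
  structure(list(quantiles = q, ks_stat = ks_uniform(q),
                 ks_ci = bootstrap_ks_ci(q, B = B, seed = seed),
                 bin_counts = counts, prop_below = proportion_below(q, alpha_list),
                 n = length(q)),
            class = "vitd_validation")
}

#' @export
print.vitd_validation <- function(x, ...) {
  cat("Predicted-quantile uniformity check (n =", x$n, ")\n")
  cat(sprintf("  KS statistic: %.3f  (95%% bootstrap CI [%.3f; %.3f])\n",
              x$ks_stat, x$ks_ci[1], x$ks_ci[2]))
  if (nrow(x$prop_below)) {
    for (i in seq_len(nrow(x$prop_below))) {
      cat(sprintf("  below the %.0f%% centile: %.1f%% observed\n",
                  100 * x$prop_below$alpha[i],
                  100 * x$prop_below$observed[i]))
    }
  }
  invisible(x)
}

#' Histogram and ECDF diagnostics of predicted quantiles
#'
#' @param x a `"vitd_validation"` object.
#' @param which `"hist"`, `"ecdf"`, or both.
#' @param ... passed to the underlying plot calls.
#' @export
plot.vitd_validation <- function(x, which = c("hist", "ecdf"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (length(which) > 1L) {
    old <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(old))
  }
  if ("hist" %in% which) {
    graphics::hist(x$quantiles, breaks = seq(0, 1, length.out =
                     length(x$bin_counts) + 1L), freq = FALSE,
                   xlab = "predicted quantile", main = "Quantile histogram",
                   ...)
    graphics::abline(h = 1, lty = 2)
  }
  if ("ecdf" %in% which) {
    graphics::plot(stats::ecdf(x$quantiles), xlim = c(0, 1),
                   xlab = "predicted quantile", main = "ECDF vs uniform",
                   ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
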