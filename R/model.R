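#' Seasonal 25(OH)D centile model object
#'
#' Bundles the ten regression coefficients of the seasonal model for
#' square-root transformed serum 25(OH)D together with the residual
#' standard deviation on that scale. The object is the unit of exchange
#' between prediction, refitting, validation and the command-line tool.
#'
#' @param beta numeric vector of length 10, ordered as [model_term_names()]:
#'   intercept, annual sin/cos, semi-annual sin/cos, t(BMI), t(BMI)^2,
#'   male low-BMI spline, female-by-annual sin/cos. Units: sqrt(nmol/L)
#'   per unit regressor.
#' @param sigma_eps residual standard deviation on the sqrt(nmol/L) scale;
#'   must be positive.
#' @param provenance free-text label recording where the coefficients come
#'   from (e.g. `"published-2015"` or `"refit-2026-01-01"`).
#' @return an object of class `"vitd_model"`.
#' @seealso [published_vitd_model()], [predict.vitd_model()], [vitd_fit()]
#' @examples
#' m <- vitd_model(c(-2.754, -1.077, -0.756, 0.188, 0.025,
#'                   -81.08, -165.6, -1174, 0.218, 0.164), 1.36)
#' predict(m, data.frame(sex = "F", bmi = 20, day = 234))
#' @export
vitd_model <- function(beta, sigma_eps, provenance = "unspecified") {
  beta <- as.numeric(beta)
  if (length(beta) != 10L || any(!is.finite(beta))) {
    stop("'beta' must be 10 finite coefficients in the fixed term order",
         call. = FALSE)
  }
  if (!is.numeric(sigma_eps) || length(sigma_eps) != 1L ||
      !is.finite(sigma_eps) || sigma_eps <= 0) {
    stop("'sigma_eps' must be a single positive number", call. = FALSE)
  }
  names(beta) <- model_term_names()
  structure(list(beta = beta, sigma_eps = as.numeric(sigma_eps),
                 provenance = as.character(provenance)[1L]),
            class = "vitd_model")
}

#' The bundled published reference model
#'
#' Returns the reference coefficient vector estimated on a Swiss
#' population-based cohort (LC-MS/MS assay scale), stored exactly at the
#' precision at which it was reported, with residual SD 1.36 sqrt(nmol/L).
#'
#' @return a [vitd_model()] object with provenance `"published-2015"`.
#' @examples
#' coef(published_vitd_model())
#' @export
published_vitd_model <- function() {
  read_vitd_model(system.file("extdata", "published-model.json",
                              package = "vitdcentile", mustWork = TRUE))
}

#' Read / write a model-coefficient file
#'
#' Models are stored as a flat key-value JSON document with fields
#' `beta0`..`beta9`, `sigma_eps`, `provenance` and `schema_version`.
#' Coefficients round-trip at full double precision, and a canonical file
#' rewritten after reading is byte-identical.
#'
#' @param path file path.
#' @return `read_vitd_model` returns a `"vitd_model"`; `write_vitd_model`
#'   returns `path` invisibly.
#' @export
read_vitd_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- paste0("beta", 0:9)
  if (!all(keys %in% names(doc))) {
    stop("model file must contain fields beta0..beta9: ", path, call. = FALSE)
  }
  if (is.null(doc$sigma_eps)) stop("model file lacks 'sigma_eps'", call. = FALSE)
  vitd_model(unlist(doc[keys]), doc$sigma_eps,
             provenance = if (is.null(doc$provenance)) "unspecified"
                          else doc$provenance)
}

#' @rdname read_vitd_model
#' @param model a `"vitd_model"` object.
#' @export
write_vitd_model <- function(model, path) {
  stopifnot(inherits(model, "vitd_model"))
  doc <- c(list(schema_version = 1L),
           stats::setNames(as.list(unname(model$beta)), paste0("beta", 0:9)),
           list(sigma_eps = model$sigma_eps, provenance = model$provenance))
  write_kv_json(doc, path)
}

#' @export
print.vitd_model <- function(x, ...) {
  cat("Seasonal 25(OH)D centile model (sqrt scale)\n")
  cat("  provenance:", x$provenance, "\n")
  cat("  residual SD (sigma_eps):", format(x$sigma_eps), "sqrt(nmol/L)\n")
  cat("  coefficients:\n")
  print(x$beta, digits = 4)
  invisible(x)
}

#' @export
coef.vitd_model <- function(object, ...) object$beta
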