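# Internal helpers.

# Run downstream RNG under `seed` without disturbing the caller's stream.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    do.call(on.exit,
            list(bquote(assign(".Random.seed", .(old), globalenv())),
                 add = TRUE), envir = envir)
  }
  set.seed(seed)
  invisible(NULL)
}

# Shortest decimal representation that round-trips to the same double.
# Keeps coefficient files both human-readable and bit-exact.
fmt_double <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("null")
    s <- "0"
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) break
    }
    s
  }, character(1))
}

# Writer for the flat key-value JSON documents (model / calibration
# files). jsonlite remains the parser; this emitter exists so that
# doubles are stored at full precision yet in their shortest form.
write_kv_json <- function(doc, path) {
  enc <- function(v) {
    if (is.character(v)) {
      paste0('"', gsub('"', '\\\\"', v), '"')
    } else if (length(v) > 1L) {
      paste0("[", paste(fmt_double(as.numeric(v)), collapse = ", "), "]")
    } else if (is.na(v)) "null"
    else if (is.integer(v)) as.character(v)
    else fmt_double(as.numeric(v))
  }
  body <- vapply(names(doc), function(k) {
    paste0('  "', k, '": ', enc(doc[[k]]))
  }, character(1))
  writeLines(c("{", paste0(body, c(rep(",", length(body) - 1L), "")), "}"),
             path)
  invisible(path)
}

# Truncated-normal draws by inverse-CDF; exact, no rejection loop.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
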