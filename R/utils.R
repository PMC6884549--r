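# Internal validation helpers shared across the assay modules.

check_number <- function(x, name, finite = TRUE, min = -Inf, max = Inf,
                         strict_min = FALSE, allow_vector = FALSE) {
  if (!is.numeric(x) || (!allow_vector && length(x) != 1L)) {
    abort(sprintf("`%s` must be %s numeric value.", name,
                  if (allow_vector) "a" else "a single"),
          class = "bertx_validation_error")
  }
  if (finite && any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite (got non-finite value).", name),
          class = "bertx_validation_error")
  }
  bad_lo <- if (strict_min) any(x <= min) else any(x < min)
  if (bad_lo || any(x > max)) {
    abort(sprintf("`%s` must lie in %s%s, %s].",
                  name, if (strict_min) "(" else "[", format(min), format(max)),
          class = "bertx_invalid_parameter")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "bertx_invalid_parameter")
  }
  invisible(as.integer(x))
}

check_probability <- function(x, name) {
  check_number(x, name, min = 0, max = 1)
}

check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column%s: %s.",
                  what, if (length(missing) > 1L) "s" else "",
                  paste0("`", missing, "`", collapse = ", ")),
          class = "bertx_schema_error")
  }
  invisible(df)
}

# Seed handling: every stochastic generator scopes its RNG with withr so the
# caller's random state is untouched and identical seeds give identical draws.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  check_count(seed, "seed", min = 0L)
  withr::local_seed(as.integer(seed), .local_envir = envir)
}
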