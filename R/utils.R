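# internal helpers shared across modules

#' Round half away from zero
#'
#' Nearest-integer rounding with ties going away from zero, the convention
#' used for all printed percentage cells (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_corequant <- function(...) {
  stop(..., call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar checks used by the constructors
assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    stop_corequant(sprintf("`%s` must be a single finite number in %s%s, %s%s",
                           name,
                           if (strict_lower) "(" else "[", format(lower),
                           format(upper), if (strict_upper) ")" else "]"))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_corequant(sprintf("%s is missing required column(s): %s",
                           what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
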