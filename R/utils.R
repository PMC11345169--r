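# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all reported currency and ratio
#' values. Base [round()] rounds half to even, which does not match how unit
#' costs and ICERs are conventionally reported.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(96.5)      # 97, not 96
#' round_half_up(97407.6923, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon absorbs binary-representation error of exact halves
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_invalid <- function(msg) stop(msg, call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_invalid(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (strict_lower && x <= lower) {
    abort_invalid(sprintf("`%s` must be > %s (got %s).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    abort_invalid(sprintf("`%s` must be >= %s (got %s).", name, lower, x))
  }
  if (x > upper) {
    abort_invalid(sprintf("`%s` must be <= %s (got %s).", name, upper, x))
  }
  invisible(x)
}

assert_fraction <- function(x, name) assert_number(x, name, lower = 0, upper = 1)
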