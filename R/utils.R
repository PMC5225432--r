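# Shared helpers: report rounding and tiny input checks.

#' Round half away from zero
#'
#' Report-style rounding (0.5 always rounds up in magnitude), matching how
#' fragment-analysis tables are conventionally printed. `base::round()` uses
#' round-half-even, which would print 1.005 as 1.00 rather than 1.01.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 3).
#' @return Numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(0.8725, 3)
#' @export
round_half_up <- function(x, digits = 3) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
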