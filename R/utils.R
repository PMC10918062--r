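# Internal helpers shared across the package.

# Signal a classed error so callers/tests can match on condition class.
stop_mirprop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "mirprop_error")))
}

format_error      <- function(msg) stop_mirprop(msg, "mirprop_format_error")
value_error       <- function(msg) stop_mirprop(msg, "mirprop_value_error")
duplicate_error   <- function(msg) stop_mirprop(msg, "mirprop_duplicate_error")
config_error      <- function(msg) stop_mirprop(msg, "mirprop_config_error")
consistency_error <- function(msg) stop_mirprop(msg, "mirprop_consistency_error")
io_error          <- function(msg) stop_mirprop(msg, "mirprop_io_error")
degenerate_error  <- function(msg) stop_mirprop(msg, "mirprop_degenerate_error")

#' Round half away from zero
#'
#' Decimal rounding with ties going up (away from zero), the convention used
#' for reported percentages; base `round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(14.7477, 1)  # 14.7
#' round_half_up(0.5, 0)      # 1
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# format a numeric at 6 significant digits, stable across runs
fmt_num <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
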