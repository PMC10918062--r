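# One-proportion test and exact binomial confidence interval. The z test
# uses the continuity-corrected statistic (the MedCalc-style calculator
# convention); an exact binomial p is available behind a flag. The interval
# is the exact Clopper-Pearson interval from Beta quantiles, whose closed
# forms at the boundaries are (alpha/2)^(1/n) * 100 and 100.

#' One-proportion test
#'
#' Tests an observed success fraction `x/n` against a null proportion `p0`.
#' The default method is the continuity-corrected z statistic
#' `z = (|x/n - p0| - 1/(2n)) / sqrt(p0 (1 - p0) / n)` with the numerator
#' floored at 0, and a two-sided normal p-value. `method = "exact"` returns
#' the two-sided exact binomial p instead (z is then `NA`).
#'
#' @param x number of successes, `0 <= x <= n`.
#' @param n number of trials, `n >= 1`.
#' @param p0 null proportion in (0, 1).
#' @param method `"z_cc"` (continuity-corrected z, default) or `"exact"`.
#' @return list with elements `z` and `p`.
#' @export
one_proportion_test <- function(x, n, p0 = 0.5, method = c("z_cc", "exact")) {
  method <- match.arg(method)
  if (n < 1) degenerate_error("one_proportion_test is undefined for n = 0")
  if (x < 0 || x > n) value_error("x must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) value_error("p0 must lie in (0, 1)")
  if (method == "exact")
    return(list(z = NA_real_, p = binom.test(x, n, p0)$p.value))
  num <- max(0, abs(x / n - p0) - 1 / (2 * n))
  z <- num / sqrt(p0 * (1 - p0) / n)
  list(z = z, p = 2 * pnorm(-z))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, reported as
#' percentages at full precision. `x = 0` forces the lower bound to 0 and
#' `x = n` forces the upper bound to 100; at `x = n` the lower bound has the
#' closed form `(alpha/2)^(1/n) * 100`.
#'
#' @param x number of successes.
#' @param n number of trials, `n >= 1`.
#' @param conf confidence level in (0, 1).
#' @return named numeric vector `c(low, high)` in percent.
#' @export
clopper_pearson_ci <- function(x, n, conf = 0.95) {
  if (conf <= 0 || conf >= 1) value_error("conf must lie in (0, 1)")
  if (n < 1) degenerate_error("interval undefined for n = 0")
  if (x < 0 || x > n) value_error("x must lie in [0, n]")
  a <- 1 - conf
  low <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  c(low = 100 * low, high = 100 * high)
}

#' Majority-direction call for a miRNA's correlated targets
#'
#' `"YES"` when inversely correlated targets outnumber positively correlated
#' ones, `"NO"` for the reverse, `"EQUAL"` on an exact tie.
#'
#' @param n_inverse,n_positive nonnegative counts of significantly inversely
#'   and positively correlated targets.
#' @return one of `"YES"`, `"NO"`, `"EQUAL"`.
#' @export
direction_call <- function(n_inverse, n_positive) {
  if (n_inverse < 0 || n_positive < 0) value_error("counts must be nonnegative")
  if (n_inverse > n_positive) "YES"
  else if (n_inverse < n_positive) "NO"
  else "EQUAL"
}
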