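# Spearman rank correlation with exact permutation p-values for small n.
# With six samples (3 + 3 designs pooled) the usual t approximation to the
# null of rho is unreliable, so for n <= 8 the p-value is computed by full
# enumeration of all n! rank orderings.

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of average ranks (ties receive their average rank).
#'
#' @param x,y numeric vectors of equal length `n >= 3`, finite values.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) value_error("x and y must have equal length")
  if (length(x) < 3L) value_error("spearman_rho requires n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    value_error("x and y must be finite")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    degenerate_error("zero rank variance: correlation undefined")
  max(-1, min(1, cor(rx, ry)))
}

# exact null distribution of rho for untied ranks of length n (cached)
perm_null_rho <- function(n) {
  key <- as.character(n)
  cached <- .mirprop_cache[[key]]
  if (!is.null(cached)) return(cached)
  perms <- function(m) {
    if (m == 1L) return(matrix(1L))
    p <- perms(m - 1L)
    do.call(rbind, lapply(seq_len(m), function(i)
      cbind(i, p + (p >= i))))
  }
  pm <- perms(n)
  s <- seq_len(n)
  # Pearson correlation of a permutation against the identity ranking
  rho <- (12 * as.vector(pm %*% s) - 3 * n * (n + 1)^2) / (n * (n^2 - 1))
  .mirprop_cache[[key]] <- rho
  rho
}

#' P-value for a Spearman correlation
#'
#' `method = "exact"` enumerates all `n!` rank orderings and returns the
#' two-sided fraction of permutations whose |rho| reaches the observed |rho|
#' (within a 1e-12 tolerance). The enumeration is over untied rank
#' orderings; when the observed vectors carry ties the p-value is an
#' approximation to the tie-conditional permutation null, which would
#' require the rank vectors themselves.
#' `method = "t_approx"` uses `t = rho * sqrt((n - 2) / (1 - rho^2))` with
#' `n - 2` degrees of freedom. `method = "auto"` (default) uses the exact
#' enumeration for `n <= 8` and the t approximation otherwise.
#'
#' @param rho observed correlation in \[-1, 1\].
#' @param n number of paired observations, `n >= 3`.
#' @param method one of `"auto"`, `"exact"`, `"t_approx"`.
#' @return two-sided p-value in (0, 1\].
#' @export
spearman_pvalue <- function(rho, n, method = c("auto", "exact", "t_approx")) {
  method <- match.arg(method)
  if (!is.finite(rho) || abs(rho) > 1 + 1e-8)
    value_error("|rho| must not exceed 1")
  rho <- max(-1, min(1, rho))
  if (n < 3L) value_error("spearman_pvalue requires n >= 3")
  if (method == "auto") method <- if (n <= 8L) "exact" else "t_approx"
  if (method == "exact") {
    if (n > 10L)
      value_error("exact enumeration is limited to n <= 10")
    null <- perm_null_rho(n)
    return(mean(abs(null) >= abs(rho) - 1e-12))
  }
  if (abs(rho) == 1) return(0)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(t), n - 2)
}
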