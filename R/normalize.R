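# Normalization: counts-per-million with optional TMM scaling factors, and
# log2 transformation. Both CPM and the TMM factors are computed here from
# first principles.

#' Construct a normalized expression matrix
#'
#' Light wrapper class around a numeric feature x sample matrix carrying the
#' normalization state: whether values are on the log2 scale and which
#' pseudocount was applied.
#'
#' @param values numeric matrix with feature rownames and sample colnames.
#' @param log2 logical; are the values log2-transformed?
#' @param pseudocount pseudocount used for the log2 transform (0 if none).
#' @return object of class `norm_matrix`.
#' @export
new_norm_matrix <- function(values, log2 = FALSE, pseudocount = 0) {
  if (!is.matrix(values) || !is.numeric(values))
    value_error("normalized matrix must be numeric")
  if (any(!is.finite(values)))
    value_error("normalized matrix must be finite")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    value_error("normalized matrix must have feature rownames and sample colnames")
  structure(values, log2 = log2, pseudocount = pseudocount,
            class = c("norm_matrix", class(values)))
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("normalized matrix: %d features x %d samples (%s scale)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "log2")))
                sprintf("log2, pseudocount %g", attr(x, "pseudocount"))
              else "linear CPM"))
  invisible(x)
}

is_log2 <- function(x) isTRUE(attr(x, "log2"))

#' Counts per million
#'
#' `value(f, s) = counts(f, s) / (lib_size(s) * factor(s)) * 1e6` with
#' `lib_size(s)` the column sum. With unit factors and no pseudocount every
#' column sums to exactly one million.
#'
#' @param counts count matrix (features x samples).
#' @param factors optional per-sample scaling factors (e.g. from
#'   [tmm_factors()]); default 1 for every sample.
#' @return a [new_norm_matrix()] on the linear CPM scale.
#' @export
cpm <- function(counts, factors = NULL) {
  validate_count_matrix(counts)
  lib <- colSums(counts)
  zero <- which(lib == 0)
  if (length(zero))
    value_error(sprintf("library size is zero for sample '%s'",
                        colnames(counts)[zero[1L]]))
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (length(factors) != ncol(counts) || any(!is.finite(factors)) ||
      any(factors <= 0))
    value_error("'factors' must be one positive real per sample")
  vals <- sweep(counts, 2L, lib * factors, "/") * 1e6
  new_norm_matrix(vals, log2 = FALSE, pseudocount = 0)
}

# weighted trimmed mean of M-values for one sample against the reference
tmm_one <- function(obs, ref, logratio_trim, abundance_trim) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) < 10L) {
    warning("fewer than 10 usable features for TMM pair; factor set to 1",
            call. = FALSE)
    return(1)
  }
  m <- log2((obs / n_obs) / (ref / n_ref))               # log-ratio
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2       # abundance
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abundance_trim) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))          # precision weighted
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values: for each sample, the scaling factor is the
#' precision-weighted mean of per-feature log2 ratios against a reference
#' sample after trimming the 30% most extreme log-ratios (M) and the 5% most
#' extreme average log-abundances (A); features with a zero count in either
#' member of the pair are excluded. The default reference is the sample whose
#' 75th-percentile count fraction is closest to the mean of those fractions.
#' Factors are rescaled so that their geometric mean is 1; CPM columns scaled
#' by them no longer sum to one million, by design.
#'
#' @param counts count matrix with at least two samples.
#' @param ref_sample optional sample id used as the reference.
#' @param logratio_trim,abundance_trim trim fractions on M and A.
#' @return named vector of positive per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        logratio_trim = 0.3, abundance_trim = 0.05) {
  validate_count_matrix(counts)
  if (ncol(counts) < 2L) value_error("TMM requires at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) value_error("TMM requires positive library sizes")
  if (is.null(ref_sample)) {
    f75 <- apply(counts, 2L, quantile, probs = 0.75) / lib
    ref_sample <- colnames(counts)[which.min(abs(f75 - mean(f75)))]
  }
  if (!ref_sample %in% colnames(counts))
    value_error(sprintf("reference sample '%s' not found", ref_sample))
  ref <- counts[, ref_sample]
  f <- vapply(seq_len(ncol(counts)), function(j)
    tmm_one(counts[, j], ref, logratio_trim, abundance_trim), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Log2-transform a normalized matrix
#'
#' @param norm a linear-scale [new_norm_matrix()].
#' @param pseudocount nonnegative value added before taking log2. A zero
#'   pseudocount is rejected when any value is zero (would produce -Inf).
#' @return a log2-scale `norm_matrix`.
#' @export
log2_transform <- function(norm, pseudocount = 1) {
  if (is_log2(norm)) value_error("matrix is already log2-transformed")
  if (!inherits(norm, "norm_matrix")) norm <- new_norm_matrix(norm)
  if (pseudocount < 0) value_error("pseudocount must be nonnegative")
  if (pseudocount == 0 && any(norm == 0))
    value_error("pseudocount 0 with zero values would produce -Inf")
  new_norm_matrix(log2(unclass(norm) + pseudocount),
                  log2 = TRUE, pseudocount = pseudocount)
}
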