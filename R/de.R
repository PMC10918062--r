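# Per-feature differential expression between two groups. Four tests are
# offered, chosen to match the experimental design: pooled-variance Student t
# and one-way ANOVA for replicated designs on log2-normalized values; Fisher
# exact and chi-squared on within-group pooled counts for replicate-free
# designs. Significance is driven by the raw p-value by default, with
# Benjamini-Hochberg adjustment behind a flag.

group_cols <- function(values, meta, group) {
  idx <- match(meta$sample[meta$group == group], colnames(values))
  if (anyNA(idx) || length(idx) == 0L)
    config_error(sprintf("group '%s' has no samples in the matrix", group))
  idx
}

de_frame <- function(feature, mean_a, mean_b, log2fc, stat, p,
                     alpha, p_adjust) {
  p_adj <- if (p_adjust == "BH") bh_adjust(p) else rep(NA_real_, length(p))
  crit <- if (p_adjust == "BH") p_adj else p
  significant <- crit < alpha
  direction <- ifelse(!significant | log2fc == 0, "none",
                      ifelse(log2fc > 0, "up", "down"))
  data.frame(feature = feature, mean_a = mean_a, mean_b = mean_b,
             log2fc = log2fc, stat = stat, p = p, p_adj = p_adj,
             significant = significant, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sample pooled-variance t test per feature
#'
#' Two-sided Student t test with pooled variance on log2-normalized values,
#' one test per feature. `log2fc = mean_b - mean_a`. Features with zero
#' variance in both groups and equal means get `stat = 0`, `p = 1`.
#'
#' @param norm log2-scale [new_norm_matrix()].
#' @param meta sample metadata (`sample`, `group`).
#' @param group_a,group_b group labels (a = reference, b = case).
#' @param alpha significance threshold.
#' @param p_adjust `"none"` (raw p drives significance) or `"BH"`.
#' @return data.frame with columns `feature`, `mean_a`, `mean_b`, `log2fc`,
#'   `stat`, `p`, `p_adj`, `significant`, `direction`.
#' @export
de_ttest <- function(norm, meta, group_a, group_b, alpha = 0.05,
                     p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!is_log2(norm)) config_error("de_ttest expects log2-scale values")
  ia <- group_cols(norm, meta, group_a)
  ib <- group_cols(norm, meta, group_b)
  na <- length(ia); nb <- length(ib)
  if (na < 2L || nb < 2L)
    config_error("de_ttest requires at least 2 samples per group")
  a <- unclass(norm)[, ia, drop = FALSE]
  b <- unclass(norm)[, ib, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, var); vb <- apply(b, 1L, var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  stat <- (mb - ma) / se
  df <- na + nb - 2
  p <- 2 * pt(-abs(stat), df)
  flat <- se == 0 & mb == ma          # constant, identical groups
  stat[flat] <- 0; p[flat] <- 1
  p[se == 0 & mb != ma] <- 0          # zero variance, distinct means
  stat[se == 0 & mb != ma] <- sign(mb - ma)[se == 0 & mb != ma] * Inf
  de_frame(rownames(norm), ma, mb, mb - ma, stat, p, alpha, p_adjust)
}

# two-sided Fisher exact p for table [[x_a, N_a - x_a], [x_b, N_b - x_b]]:
# sum of hypergeometric point probabilities not exceeding the observed one
# (with a small relative slack for floating-point ties).
fisher_p <- function(xa, na_, xb, nb_) {
  m <- xa + xb
  if (m == 0 || m == na_ + nb_ || na_ == 0 || nb_ == 0) return(NA_real_)
  support <- max(0, m - nb_):min(m, na_)
  d <- dhyper(support, m, na_ + nb_ - m, na_)
  obs <- dhyper(xa, m, na_ + nb_ - m, na_)
  min(1, sum(d[d <= obs * (1 + 1e-12)]))
}

#' Fisher exact test on pooled counts per feature
#'
#' Counts are pooled within group; for each feature the 2x2 table
#' `[[x_a, N_a - x_a], [x_b, N_b - x_b]]` (N = pooled library size) is tested
#' with the two-sided Fisher exact test. `log2fc` is computed from pooled
#' group CPM with a pseudocount of 0.5. A degenerate margin yields `p = 1`
#' with a logged note.
#'
#' @inheritParams de_ttest
#' @param counts count matrix.
#' @return see [de_ttest()].
#' @export
de_fisher <- function(counts, meta, group_a, group_b, alpha = 0.05,
                      p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  validate_count_matrix(counts)
  ia <- group_cols(counts, meta, group_a)
  ib <- group_cols(counts, meta, group_b)
  xa <- rowSums(counts[, ia, drop = FALSE])
  xb <- rowSums(counts[, ib, drop = FALSE])
  na_ <- sum(xa); nb_ <- sum(xb)
  p <- vapply(seq_along(xa), function(i) fisher_p(xa[i], na_, xb[i], nb_),
              numeric(1))
  n_deg <- sum(is.na(p))
  if (n_deg > 0)
    message(sprintf("de_fisher: %d features with a zero margin (p set to 1)",
                    n_deg))
  p[is.na(p)] <- 1
  cpm_a <- (xa + 0.5) / na_ * 1e6
  cpm_b <- (xb + 0.5) / nb_ * 1e6
  lfc <- log2(cpm_b / cpm_a)
  de_frame(rownames(counts), cpm_a, cpm_b, lfc, stat = rep(NA_real_, length(p)),
           p, alpha, p_adjust)
}

#' Pearson chi-squared test on pooled counts per feature
#'
#' Same 2x2 tables as [de_fisher()], tested with the Pearson chi-squared
#' statistic (1 df, no continuity correction). A zero expected cell yields
#' `p = 1` with a logged note.
#'
#' @inheritParams de_fisher
#' @return see [de_ttest()].
#' @export
de_chisq <- function(counts, meta, group_a, group_b, alpha = 0.05,
                     p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  validate_count_matrix(counts)
  ia <- group_cols(counts, meta, group_a)
  ib <- group_cols(counts, meta, group_b)
  xa <- rowSums(counts[, ia, drop = FALSE])
  xb <- rowSums(counts[, ib, drop = FALSE])
  na_ <- sum(xa); nb_ <- sum(xb)
  # chi2 = N (ad - bc)^2 / (r1 r2 c1 c2) on [[a=xa, b=na-xa], [c=xb, d=nb-xb]]
  n_tot <- na_ + nb_
  c1 <- xa + xb; c2 <- n_tot - c1
  stat <- n_tot * (xa * (nb_ - xb) - (na_ - xa) * xb)^2 /
    (as.numeric(na_) * nb_ * c1 * c2)
  deg <- c1 == 0 | c2 == 0 | na_ == 0 | nb_ == 0
  if (any(deg))
    message(sprintf("de_chisq: %d features with a zero expected cell (p set to 1)",
                    sum(deg)))
  stat[deg] <- 0
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  p[deg] <- 1
  cpm_a <- (xa + 0.5) / na_ * 1e6
  cpm_b <- (xb + 0.5) / nb_ * 1e6
  de_frame(rownames(counts), cpm_a, cpm_b, log2(cpm_b / cpm_a), stat, p,
           alpha, p_adjust)
}

#' One-way fixed-effects ANOVA per feature
#'
#' F test across two or more groups on log2-normalized values. With exactly
#' two groups `F = t^2` of [de_ttest()] and the p-values coincide; `log2fc`
#' and `direction` are then reported as in the t test, otherwise `log2fc` is
#' `NA` and `direction` is `"none"`.
#'
#' @inheritParams de_ttest
#' @param groups character vector of two or more group labels.
#' @return see [de_ttest()].
#' @export
de_anova <- function(norm, meta, groups, alpha = 0.05,
                     p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!is_log2(norm)) config_error("de_anova expects log2-scale values")
  if (length(groups) < 2L) config_error("de_anova requires at least 2 groups")
  idx <- lapply(groups, function(g) group_cols(norm, meta, g))
  sizes <- lengths(idx)
  if (any(sizes < 2L))
    config_error("de_anova requires at least 2 samples in every group")
  vals <- unclass(norm)
  k <- length(groups)
  n_tot <- sum(sizes)
  gm <- vapply(idx, function(i) rowMeans(vals[, i, drop = FALSE]),
               numeric(nrow(vals)))
  gv <- vapply(idx, function(i) apply(vals[, i, drop = FALSE], 1L, var),
               numeric(nrow(vals)))
  if (!is.matrix(gm)) { gm <- matrix(gm, nrow = 1L); gv <- matrix(gv, nrow = 1L) }
  grand <- as.vector(gm %*% sizes) / n_tot
  ssb <- rowSums(sweep(gm, 1L, grand, "-")^2 %*% diag(sizes))
  ssw <- as.vector(gv %*% (sizes - 1))
  msb <- ssb / (k - 1); msw <- ssw / (n_tot - k)
  f <- msb / msw
  p <- pf(f, k - 1, n_tot - k, lower.tail = FALSE)
  flat <- ssw == 0 & ssb < 1e-24
  f[flat] <- 0; p[flat] <- 1
  sep <- ssw == 0 & ssb >= 1e-24
  f[sep] <- Inf; p[sep] <- 0
  if (k == 2L) {
    lfc <- gm[, 2L] - gm[, 1L]
    ma <- gm[, 1L]; mb <- gm[, 2L]
  } else {
    lfc <- rep(NA_real_, nrow(vals)); ma <- grand; mb <- grand
  }
  out <- de_frame(rownames(vals), ma, mb, lfc, f, p, alpha, p_adjust)
  if (k > 2L) out$direction <- "none"
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) value_error("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Summary counts of a differential-expression run
#'
#' @param n_total,n_significant,n_up,n_down integer counts;
#'   `n_up + n_down` must equal `n_significant`.
#' @return list of class `de_summary` with the four counts and
#'   `pct_significant` (over `n_total`), `pct_up`, `pct_down` (over
#'   `n_significant`), percentages rounded half-up to 1 decimal.
#' @export
de_summary <- function(n_total, n_significant, n_up, n_down) {
  if (n_up + n_down != n_significant)
    value_error("n_up + n_down must equal n_significant")
  if (n_significant > n_total)
    value_error("n_significant cannot exceed n_total")
  if (n_significant == 0)
    message("de_summary: no significant features; pct_up/pct_down set to 0")
  pct <- function(x, d) if (d == 0) 0 else round_half_up(100 * x / d, 1)
  structure(list(n_total = n_total, n_significant = n_significant,
                 n_up = n_up, n_down = n_down,
                 pct_significant = pct(n_significant, n_total),
                 pct_up = pct(n_up, n_significant),
                 pct_down = pct(n_down, n_significant)),
            class = "de_summary")
}

#' @export
print.de_summary <- function(x, ...) {
  cat(sprintf("%d of %d features significant (%.1f%%): %d up (%.1f%%), %d down (%.1f%%)\n",
              x$n_significant, x$n_total, x$pct_significant,
              x$n_up, x$pct_up, x$n_down, x$pct_down))
  invisible(x)
}

#' Summarize a differential-expression table
#'
#' Recomputes significance at `alpha` from the raw p-values and tallies up-
#' and downregulated features by the sign of `log2fc`.
#'
#' @param de data.frame from one of the `de_*` functions.
#' @param alpha significance threshold applied to the raw p-value.
#' @return a [de_summary()].
#' @export
summarize_de <- function(de, alpha = 0.05) {
  sig <- de$p < alpha
  de_summary(nrow(de), sum(sig),
             sum(sig & de$log2fc > 0), sum(sig & de$log2fc < 0))
}
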