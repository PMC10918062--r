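# The core integration analysis: for each focus miRNA, correlate its
# expression with its predicted, differentially expressed mRNA targets
# across all samples (both groups pooled), classify each pair by sign and
# correlation significance, and test whether the inversely correlated
# fraction departs from one half.

#' Correlate one miRNA against its predicted targets
#'
#' One record is produced per target gene that is in the significant mRNA
#' set and present in the expression matrix; targets failing either filter
#' are dropped with a logged count. Correlation is Spearman across all
#' samples of the pooled design; pairs with zero rank variance are dropped
#' with a logged count. Each record is classified `inverse` (`rho < 0`,
#' `p < alpha_corr`), `positive` (`rho > 0`, `p < alpha_corr`) or
#' `nonsignificant`.
#'
#' @param mirna miRNA identifier (must be a row of `mirna_expr`).
#' @param targets character vector of predicted target gene identifiers.
#' @param mirna_expr,mrna_expr log2-scale [new_norm_matrix()] objects sharing
#'   the same samples in the same order.
#' @param de_mrna_sig character vector of significantly differentially
#'   expressed genes (the mRNA-side filter).
#' @param alpha_corr per-pair correlation significance threshold.
#' @param method p-value method passed to [spearman_pvalue()].
#' @return data.frame with columns `mirna`, `gene`, `rho`, `p`, `n`, `cls`.
#' @export
correlate_targets <- function(mirna, targets, mirna_expr, mrna_expr,
                              de_mrna_sig, alpha_corr = 0.05,
                              method = "auto") {
  if (!identical(colnames(mirna_expr), colnames(mrna_expr)))
    consistency_error("miRNA and mRNA matrices must share samples and order")
  if (!mirna %in% rownames(mirna_expr))
    consistency_error(sprintf("miRNA '%s' absent from expression matrix", mirna))
  usable <- intersect(targets, de_mrna_sig)
  n_not_sig <- length(targets) - length(usable)
  in_expr <- usable[usable %in% rownames(mrna_expr)]
  n_missing <- length(usable) - length(in_expr)
  if (n_missing > 0)
    message(sprintf("correlate_targets(%s): %d significant targets absent from expression matrix",
                    mirna, n_missing))
  empty <- data.frame(mirna = character(), gene = character(),
                      rho = numeric(), p = numeric(), n = integer(),
                      cls = character(), stringsAsFactors = FALSE)
  if (length(in_expr) == 0L) {
    message(sprintf("correlate_targets(%s): no usable targets (%d filtered as not significant)",
                    mirna, n_not_sig))
    return(empty)
  }
  x <- as.numeric(unclass(mirna_expr)[mirna, ])
  n <- length(x)
  rec <- lapply(in_expr, function(g) {
    y <- as.numeric(unclass(mrna_expr)[g, ])
    rho <- tryCatch(spearman_rho(x, y),
                    mirprop_degenerate_error = function(e) NA_real_)
    if (is.na(rho)) return(NULL)
    p <- spearman_pvalue(rho, n, method = method)
    cls <- if (p < alpha_corr && rho < 0) "inverse"
           else if (p < alpha_corr && rho > 0) "positive"
           else "nonsignificant"
    data.frame(mirna = mirna, gene = g, rho = rho, p = p, n = n, cls = cls,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rec, is.null, logical(1)))
  if (dropped > 0)
    message(sprintf("correlate_targets(%s): %d pairs dropped (zero rank variance)",
                    mirna, dropped))
  rec <- rec[!vapply(rec, is.null, logical(1))]
  if (length(rec) == 0L) return(empty)
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}

#' Integrate miRNA and mRNA expression by inverse-correlation proportion
#'
#' The central fitting function. For each focus miRNA its predicted,
#' significantly differentially expressed targets are Spearman-correlated
#' with the miRNA across all samples; among the significantly correlated
#' targets the fraction that are inversely correlated is tested against
#' `p0` with the continuity-corrected one-proportion test, an exact
#' Clopper-Pearson interval is attached, and a majority-direction call is
#' made. A miRNA is a candidate regulator when the proportion test is
#' significant at `alpha_prop` and the call is `"YES"`; its inversely
#' correlated targets form the candidate pair set.
#'
#' miRNAs with fewer than `min_targets` significantly correlated targets are
#' excluded from testing and counted in a logged note.
#'
#' @param focus a `mirna_selection` from [intersect_with_de()], or a
#'   character vector of miRNA identifiers.
#' @param target_map data.frame of (`mirna`, `gene`) pairs.
#' @param mirna_expr,mrna_expr log2-scale [new_norm_matrix()] objects with
#'   identical samples.
#' @param de_mirna miRNA differential-expression table (provides the
#'   expression direction reported per candidate).
#' @param de_mrna_sig character vector of significant mRNA identifiers.
#' @param alpha_corr per-pair correlation threshold.
#' @param alpha_prop proportion-test threshold.
#' @param p0 null proportion of inverse among significantly correlated
#'   targets.
#' @param min_targets minimum number of significantly correlated targets for
#'   the proportion test to be attempted.
#' @param conf confidence level of the Clopper-Pearson interval.
#' @param prop_method `"z_cc"` or `"exact"`, see [one_proportion_test()].
#' @param corr_method Spearman p-value method, see [spearman_pvalue()].
#' @return object of class `mirprop`: a list with `proportion` (one row per
#'   tested miRNA, ordered by p then identifier), `correlations` (all pair
#'   records), `candidates` (named list of inverse target vectors),
#'   `n_skipped`, and the call. Methods: `print`, `summary`, `plot`,
#'   `as.data.frame`.
#' @export
integrate_mirna <- function(focus, target_map, mirna_expr, mrna_expr,
                            de_mirna, de_mrna_sig,
                            alpha_corr = 0.05, alpha_prop = 0.05, p0 = 0.5,
                            min_targets = 2, conf = 0.95,
                            prop_method = "z_cc", corr_method = "auto") {
  ids <- if (inherits(focus, "mirna_selection")) focus$focus_set else focus
  miss <- setdiff(ids, rownames(mirna_expr))
  if (length(miss))
    consistency_error(sprintf("focus miRNA '%s' absent from expression matrix",
                              miss[1L]))
  cors <- list(); rows <- list(); cands <- list()
  n_skipped <- 0L
  for (id in ids) {
    targets <- target_map$gene[target_map$mirna == id]
    rec <- correlate_targets(id, targets, mirna_expr, mrna_expr,
                             de_mrna_sig, alpha_corr, method = corr_method)
    cors[[id]] <- rec
    n_inv <- sum(rec$cls == "inverse")
    n_pos <- sum(rec$cls == "positive")
    n_sig <- n_inv + n_pos
    if (n_sig < min_targets) { n_skipped <- n_skipped + 1L; next }
    pt_ <- one_proportion_test(n_inv, n_sig, p0, method = prop_method)
    ci <- clopper_pearson_ci(n_inv, n_sig, conf)
    dirn <- direction_call(n_inv, n_pos)
    de_row <- match(id, de_mirna$feature)
    fgr <- if (is.na(de_row) || is.na(de_mirna$log2fc[de_row])) NA_character_
           else if (de_mirna$log2fc[de_row] > 0) "up" else "down"
    rows[[id]] <- data.frame(
      mirna = id, n_sig = n_sig, n_inverse = n_inv, n_positive = n_pos,
      p_hat = n_inv / n_sig, z = pt_$z, p = pt_$p,
      ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
      direction = dirn, fgr_direction = fgr, stringsAsFactors = FALSE)
    if (pt_$p < alpha_prop && dirn == "YES")
      cands[[id]] <- rec$gene[rec$cls == "inverse"]
  }
  if (n_skipped > 0)
    message(sprintf("integrate_mirna: %d miRNAs with fewer than %d significantly correlated targets (not tested)",
                    n_skipped, min_targets))
  prop <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), n_sig = integer(), n_inverse = integer(),
               n_positive = integer(), p_hat = numeric(), z = numeric(),
               p = numeric(), ci_low = numeric(), ci_high = numeric(),
               direction = character(), fgr_direction = character(),
               stringsAsFactors = FALSE)
  prop <- prop[order(prop$p, prop$mirna), , drop = FALSE]
  rownames(prop) <- NULL
  all_cors <- if (length(cors)) do.call(rbind, cors) else NULL
  if (!is.null(all_cors)) rownames(all_cors) <- NULL
  structure(list(proportion = prop,
                 correlations = all_cors %||% data.frame(),
                 candidates = if (length(cands)) cands[order(names(cands))] else cands,
                 n_focus = length(ids), n_tested = nrow(prop),
                 n_skipped = n_skipped,
                 params = list(alpha_corr = alpha_corr,
                               alpha_prop = alpha_prop, p0 = p0,
                               min_targets = min_targets, conf = conf,
                               prop_method = prop_method,
                               corr_method = corr_method),
                 call = match.call()),
            class = "mirprop")
}

#' @export
print.mirprop <- function(x, ...) {
  cat("miRNA-mRNA inverse-correlation integration\n")
  cat(sprintf("  focus miRNAs: %d (tested: %d, below min_targets: %d)\n",
              x$n_focus, x$n_tested, x$n_skipped))
  cat(sprintf("  candidate regulators (p < %g, majority inverse): %d\n",
              x$params$alpha_prop, length(x$candidates)))
  if (length(x$candidates))
    cat("  ", paste(names(x$candidates), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mirprop <- function(object, ...) {
  cat("Proportion-test results (ordered by p):\n")
  df <- object$proportion
  if (nrow(df)) {
    show <- df
    show$p_hat <- round(show$p_hat, 3)
    show$p <- signif(show$p, 3)
    show$ci_low <- round(show$ci_low, 2)
    show$ci_high <- round(show$ci_high, 2)
    print(show, row.names = FALSE)
  } else cat("  (no miRNA reached the minimum number of correlated targets)\n")
  invisible(object$proportion)
}

#' @export
as.data.frame.mirprop <- function(x, ...) x$proportion

#' Confidence-interval plot of the inverse-correlated fraction
#'
#' One point per tested miRNA at the observed inverse fraction (percent),
#' with its exact confidence interval; the null proportion is drawn as a
#' dashed line.
#'
#' @param x a `mirprop` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mirprop <- function(x, ...) {
  df <- x$proportion
  if (nrow(df) == 0L) {
    warning("nothing to plot: no tested miRNA", call. = FALSE)
    return(invisible(x))
  }
  k <- nrow(df)
  plot(100 * df$p_hat, seq_len(k), xlim = c(0, 100), yaxt = "n",
       xlab = "inversely correlated targets (%)", ylab = "",
       pch = 19, ...)
  axis(2, at = seq_len(k), labels = df$mirna, las = 2, cex.axis = 0.6)
  arrows(df$ci_low, seq_len(k), df$ci_high, seq_len(k),
         angle = 90, code = 3, length = 0.02)
  abline(v = 100 * x$params$p0, lty = 2)
  invisible(x)
}
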