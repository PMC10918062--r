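# Abundance-based selection: rank miRNAs by mean normalized count within the
# case group, keep the top N, and intersect with the significant-DE set to
# form the focus set handed to the integration stage.

#' Top-N miRNAs by abundance in one group
#'
#' miRNAs ranked by their mean normalized count over the group's samples,
#' descending; ties are broken by feature identifier, ascending, so the
#' ordering is total and re-running is deterministic.
#'
#' @param norm [new_norm_matrix()] (linear CPM scale recommended for
#'   ranking).
#' @param meta sample metadata.
#' @param group group label whose samples define the ranking.
#' @param n number of top features to return; clamped to the number of
#'   features available.
#' @return data.frame with columns `rank`, `mirna`, `group_mean`.
#' @export
top_n_by_abundance <- function(norm, meta, group, n = 100) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0)
    value_error("'n' must be a positive integer")
  idx <- group_cols(norm, meta, group)
  means <- rowMeans(unclass(norm)[, idx, drop = FALSE])
  ord <- order(-means, rownames(norm))
  keep <- ord[seq_len(min(n, length(means)))]
  data.frame(rank = seq_along(keep),
             mirna = rownames(norm)[keep],
             group_mean = unname(means[keep]),
             stringsAsFactors = FALSE)
}

#' Intersect the abundance ranking with the significant-DE set
#'
#' The focus set consists of the top-ranked miRNAs that are significantly
#' differentially expressed at `alpha` (raw p), in ranking order.
#'
#' @param top data.frame from [top_n_by_abundance()].
#' @param de differential-expression table covering every miRNA in `top`.
#' @param alpha significance threshold applied to the raw p-value.
#' @return list of class `mirna_selection` with elements `top` (the ranking
#'   plus an `in_focus_set` flag), `focus_set` (character, ordered), `n_top`,
#'   `n_focus`.
#' @export
intersect_with_de <- function(top, de, alpha = 0.05) {
  miss <- setdiff(top$mirna, de$feature)
  if (length(miss))
    consistency_error(sprintf(
      "%d ranked miRNAs absent from the DE table (first: '%s')",
      length(miss), miss[1L]))
  sig <- de$feature[de$p < alpha]
  top$in_focus_set <- top$mirna %in% sig
  focus <- top$mirna[top$in_focus_set]
  if (length(focus) == 0L)
    warning("focus set is empty: no ranked miRNA is significant", call. = FALSE)
  structure(list(top = top, focus_set = focus,
                 n_top = nrow(top), n_focus = length(focus)),
            class = "mirna_selection")
}

#' @export
print.mirna_selection <- function(x, ...) {
  cat(sprintf("top %d miRNAs by abundance; %d in focus set (significant DE)\n",
              x$n_top, x$n_focus))
  invisible(x)
}
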