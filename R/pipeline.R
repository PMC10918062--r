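# File-based pipeline. Stages communicate exclusively through TSV files in a
# run directory, so `run_pipeline()` is literally the sequential composition
# of the individually runnable stage functions, and two runs with the same
# configuration and seed produce byte-identical outputs (recorded as MD5
# hashes in the manifest).

#' Pipeline run configuration
#'
#' All run-level constants in one validated object. Defaults mirror the
#' motivating analysis: top 100 miRNAs by case-group abundance, alpha 0.05
#' throughout, null proportion 0.5, CPM normalization with log2 pseudocount
#' 1, Student t test for the replicated two-group design.
#'
#' @param mirna_counts,mrna_counts,metadata,target_map input file paths;
#'   not required when `simulate` is given.
#' @param simulate optional [sim_config()]; when set, inputs are generated
#'   into the run directory first.
#' @param group_control,group_case group labels.
#' @param test miRNA DE test: `"ttest"`, `"fisher"`, `"chisq"` or `"anova"`.
#' @param alpha_de,alpha_corr,alpha_prop significance thresholds.
#' @param top_n abundance cut for the selection stage.
#' @param min_targets minimum significantly correlated targets per tested
#'   miRNA.
#' @param normalization `"cpm+tmm"` (TMM factors on top of library-size
#'   normalization, the default) or plain `"cpm"`.
#' @param pseudocount log2 pseudocount on the CPM scale.
#' @param p0 null proportion for the one-proportion test.
#' @param target_dialect,target_mirna_col,target_gene_col target-map parsing
#'   options, see [read_target_map()].
#' @param seed integer seed (used by the simulate stage).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(mirna_counts = NULL, mrna_counts = NULL,
                       metadata = NULL, target_map = NULL, simulate = NULL,
                       group_control = "control", group_case = "restricted",
                       test = c("ttest", "fisher", "chisq", "anova"),
                       alpha_de = 0.05, alpha_corr = 0.05, alpha_prop = 0.05,
                       top_n = 100, min_targets = 2,
                       normalization = c("cpm+tmm", "cpm"), pseudocount = 1,
                       p0 = 0.5, target_dialect = "two-column",
                       target_mirna_col = "miRNA",
                       target_gene_col = "Gene Symbol", seed = 1) {
  test <- match.arg(test)
  normalization <- match.arg(normalization)
  for (a in c(alpha_de, alpha_corr, alpha_prop))
    if (a <= 0 || a >= 1) config_error("alpha values must lie in (0, 1)")
  if (top_n < 1) config_error("top_n must be >= 1")
  if (p0 <= 0 || p0 >= 1) config_error("p0 must lie in (0, 1)")
  if (is.null(simulate)) {
    paths <- c(mirna_counts = mirna_counts, mrna_counts = mrna_counts,
               metadata = metadata, target_map = target_map)
    if (length(paths) < 4L)
      config_error("all four input paths are required unless 'simulate' is set")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      config_error(sprintf("input file not found: %s", missing[1L]))
  } else if (!inherits(simulate, "sim_config")) {
    simulate <- do.call(sim_config, simulate)
  }
  structure(list(mirna_counts = mirna_counts, mrna_counts = mrna_counts,
                 metadata = metadata, target_map = target_map,
                 simulate = simulate, group_control = group_control,
                 group_case = group_case, test = test, alpha_de = alpha_de,
                 alpha_corr = alpha_corr, alpha_prop = alpha_prop,
                 top_n = top_n, min_targets = min_targets,
                 normalization = normalization, pseudocount = pseudocount,
                 p0 = p0, target_dialect = target_dialect,
                 target_mirna_col = target_mirna_col,
                 target_gene_col = target_gene_col, seed = seed),
            class = "run_config")
}

in_path <- function(dir, name) file.path(dir, "inputs", name)

#' Stage: materialize inputs into the run directory
#'
#' Either generates a synthetic dataset (when the configuration carries a
#' `simulate` block) or copies the four input files, so that later stages
#' always read from `<dir>/inputs/`.
#'
#' @param dir run directory.
#' @param config a [run_config()].
#' @return `dir`, invisibly.
#' @export
stage_inputs <- function(dir, config) {
  dir.create(file.path(dir, "inputs"), recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$simulate)) {
    sim <- simulate_dataset(config$simulate)
    write_dataset(sim, file.path(dir, "inputs"))
  } else {
    file.copy(config$mirna_counts, in_path(dir, "mirna_counts.tsv"),
              overwrite = TRUE)
    file.copy(config$mrna_counts, in_path(dir, "mrna_counts.tsv"),
              overwrite = TRUE)
    file.copy(config$metadata, in_path(dir, "metadata.tsv"), overwrite = TRUE)
    file.copy(config$target_map, in_path(dir, "target_map.tsv"),
              overwrite = TRUE)
  }
  invisible(dir)
}

#' Stage: normalization
#'
#' Reads the raw count matrices and writes linear CPM (for ranking) and log2
#' CPM matrices, with TMM factors when the configuration asks for them.
#'
#' @inheritParams stage_inputs
#' @return `dir`, invisibly.
#' @export
stage_normalize <- function(dir, config) {
  dir.create(file.path(dir, "normalized"), showWarnings = FALSE)
  for (omic in c("mirna", "mrna")) {
    counts <- read_count_matrix(in_path(dir, paste0(omic, "_counts.tsv")))
    factors <- if (config$normalization == "cpm+tmm") tmm_factors(counts)
               else NULL
    lin <- cpm(counts, factors)
    l2 <- log2_transform(lin, config$pseudocount)
    write_norm_matrix(lin, file.path(dir, "normalized",
                                     paste0(omic, "_cpm.tsv")))
    write_norm_matrix(l2, file.path(dir, "normalized",
                                    paste0(omic, "_log2cpm.tsv")))
  }
  invisible(dir)
}

run_de <- function(test, counts, l2, meta, ga, gb, alpha) {
  switch(test,
         ttest = de_ttest(l2, meta, ga, gb, alpha),
         anova = de_anova(l2, meta, c(ga, gb), alpha),
         fisher = de_fisher(counts, meta, ga, gb, alpha),
         chisq = de_chisq(counts, meta, ga, gb, alpha))
}

#' Stage: differential expression
#'
#' Runs the configured test on the miRNA matrix and the pooled-variance t
#' test on the mRNA matrix (the mRNA side only feeds the significance filter
#' of the integration stage), and writes the DE tables plus the miRNA
#' summary counts.
#'
#' @inheritParams stage_inputs
#' @return `dir`, invisibly.
#' @export
stage_de <- function(dir, config) {
  dir.create(file.path(dir, "de"), showWarnings = FALSE)
  meta <- read_metadata(in_path(dir, "metadata.tsv"))
  ga <- config$group_control; gb <- config$group_case
  for (omic in c("mirna", "mrna")) {
    counts <- read_count_matrix(in_path(dir, paste0(omic, "_counts.tsv")))
    l2 <- read_norm_matrix(file.path(dir, "normalized",
                                     paste0(omic, "_log2cpm.tsv")),
                           log2 = TRUE, pseudocount = config$pseudocount)
    test <- if (omic == "mirna") config$test else "ttest"
    de <- run_de(test, counts, l2, meta, ga, gb, config$alpha_de)
    write_results_table(de, file.path(dir, "de", paste0("de_", omic, ".tsv")))
    if (omic == "mirna") {
      s <- summarize_de(de, config$alpha_de)
      write_results_table(
        data.frame(n_total = s$n_total, n_significant = s$n_significant,
                   n_up = s$n_up, n_down = s$n_down,
                   pct_significant = s$pct_significant, pct_up = s$pct_up,
                   pct_down = s$pct_down),
        file.path(dir, "de", "de_summary.tsv"))
    }
  }
  invisible(dir)
}

#' Stage: abundance selection
#'
#' Ranks miRNAs by mean CPM in the case group, keeps the top N and flags the
#' focus set (intersection with the significant miRNAs).
#'
#' @inheritParams stage_inputs
#' @return `dir`, invisibly.
#' @export
stage_select <- function(dir, config) {
  meta <- read_metadata(in_path(dir, "metadata.tsv"))
  lin <- read_norm_matrix(file.path(dir, "normalized", "mirna_cpm.tsv"))
  de <- read_results_table(file.path(dir, "de", "de_mirna.tsv"))
  top <- top_n_by_abundance(lin, meta, config$group_case, config$top_n)
  sel <- intersect_with_de(top, de, config$alpha_de)
  write_results_table(sel$top, file.path(dir, "selection.tsv"))
  invisible(dir)
}

#' Stage: integration
#'
#' Runs [integrate_mirna()] on the focus set and writes the correlation
#' records, the proportion-test table (Table-1-shaped, with the Yes/No/=
#' call and the miRNA's own expression direction) and the candidate
#' regulator-target hand-off file.
#'
#' @inheritParams stage_inputs
#' @return the `mirprop` object, invisibly.
#' @export
stage_integrate <- function(dir, config) {
  dir.create(file.path(dir, "integration"), showWarnings = FALSE)
  sel_tab <- read_results_table(file.path(dir, "selection.tsv"))
  focus <- sel_tab$mirna[sel_tab$in_focus_set == "TRUE" |
                           sel_tab$in_focus_set == TRUE]
  tmap <- read_target_map(in_path(dir, "target_map.tsv"),
                          dialect = config$target_dialect,
                          mirna_col = config$target_mirna_col,
                          gene_col = config$target_gene_col)
  mirna_l2 <- read_norm_matrix(file.path(dir, "normalized", "mirna_log2cpm.tsv"),
                               log2 = TRUE, pseudocount = config$pseudocount)
  mrna_l2 <- read_norm_matrix(file.path(dir, "normalized", "mrna_log2cpm.tsv"),
                              log2 = TRUE, pseudocount = config$pseudocount)
  de_mirna <- read_results_table(file.path(dir, "de", "de_mirna.tsv"))
  de_mrna <- read_results_table(file.path(dir, "de", "de_mrna.tsv"))
  fit <- integrate_mirna(focus, tmap, mirna_l2, mrna_l2, de_mirna,
                         de_mrna$feature[de_mrna$p < config$alpha_de],
                         alpha_corr = config$alpha_corr,
                         alpha_prop = config$alpha_prop, p0 = config$p0,
                         min_targets = config$min_targets)
  write_results_table(fit$correlations,
                      file.path(dir, "integration", "correlations.tsv"))
  prop <- fit$proportion
  prop$inversely_related <- c(YES = "Yes", NO = "No", EQUAL = "=")[prop$direction]
  write_results_table(
    prop[, c("mirna", "p", "ci_low", "ci_high", "inversely_related",
             "fgr_direction", "n_sig", "n_inverse")],
    file.path(dir, "integration", "proportion.tsv"))
  cand <- data.frame(
    mirna = names(fit$candidates) %||% character(0),
    inverse_targets = unname(vapply(fit$candidates, paste, "", collapse = ";")),
    stringsAsFactors = FALSE)
  write_results_table(cand, file.path(dir, "integration", "candidates.tsv"))
  invisible(fit)
}

#' Stage: recovery report
#'
#' When the inputs carry simulation ground truth, scores the called
#' candidates against it.
#'
#' @inheritParams stage_inputs
#' @return `dir`, invisibly (no-op without ground truth).
#' @export
stage_recovery <- function(dir, config) {
  truth_path <- in_path(dir, "truth_pairs.tsv")
  de_path <- in_path(dir, "truth_de_mirnas.tsv")
  if (!file.exists(truth_path) || !file.exists(de_path)) return(invisible(dir))
  pairs <- read_results_table(truth_path)
  tde <- read_results_table(de_path)
  truth <- list(regulators = tde$mirna[tde$regulator == "TRUE" |
                                         tde$regulator == TRUE],
                regulated_pairs = pairs)
  cand <- read_results_table(file.path(dir, "integration", "candidates.tsv"))
  called_pairs <- if (nrow(cand) == 0L)
    data.frame(mirna = character(), gene = character()) else
    do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
      data.frame(mirna = cand$mirna[i],
                 gene = strsplit(cand$inverse_targets[i], ";", fixed = TRUE)[[1L]],
                 stringsAsFactors = FALSE)))
  rep_ <- recovery_report(truth, cand$mirna, called_pairs)
  write_results_table(rep_, file.path(dir, "recovery.tsv"))
  invisible(dir)
}

#' Run the full pipeline
#'
#' Executes the stages in order (inputs, normalize, de, select, integrate,
#' recovery) and writes a manifest recording the resolved configuration, the
#' seed and the MD5 hash of every output file. Identical configuration and
#' seed give identical manifests.
#'
#' @param config a [run_config()].
#' @param dir run directory (created if needed).
#' @return list with the run `dir`, the `manifest` path and the `mirprop`
#'   fit, invisibly.
#' @export
run_pipeline <- function(config, dir) {
  if (!inherits(config, "run_config")) config_error("'config' must be a run_config")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(config)
  cfg$simulate <- if (is.null(cfg$simulate)) NULL else unclass(cfg$simulate)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  stage_inputs(dir, config)
  stage_normalize(dir, config)
  stage_de(dir, config)
  stage_select(dir, config)
  fit <- stage_integrate(dir, config)
  stage_recovery(dir, config)
  manifest <- write_manifest(dir, config)
  invisible(list(dir = dir, manifest = manifest, fit = fit))
}

write_manifest <- function(dir, config) {
  files <- sort(setdiff(
    list.files(dir, recursive = TRUE, full.names = FALSE), "manifest.tsv"))
  md5 <- unname(tools::md5sum(file.path(dir, files)))
  man <- data.frame(file = files, md5 = md5, stringsAsFactors = FALSE)
  man <- rbind(data.frame(file = "#seed", md5 = as.character(config$seed),
                          stringsAsFactors = FALSE), man)
  path <- file.path(dir, "manifest.tsv")
  write_results_table(man, path)
  path
}
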