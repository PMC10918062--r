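# Seeded two-omics simulator. Negative-binomial counts with log-normal
# feature means, planted differential expression on a subset of miRNAs, a
# random target map, and inverse (or positive) coupling of regulator miRNAs
# onto their targets' latent means. The simulator is the ground-truth
# benchmark for the whole pipeline.

#' Simulation configuration
#'
#' Defaults emulate the motivating study design: two groups (control vs
#' caloric restricted) of 3 biological replicates, 1546 miRNAs, several
#' thousand mRNAs, ~15% differentially expressed miRNAs, and 16 regulator
#' miRNAs whose targets are predominantly inversely coupled.
#'
#' @param n_mirna,n_mrna numbers of miRNA and mRNA features.
#' @param n_per_group biological replicates per group.
#' @param frac_de_mirna fraction of miRNAs with planted differential
#'   expression.
#' @param lfc_de magnitude of the planted log2 fold change (sign is random
#'   per feature).
#' @param targets_per_mirna predicted targets per miRNA, drawn without
#'   replacement from the mRNA pool.
#' @param n_regulators number of regulator miRNAs (a subset of the DE
#'   miRNAs, drawn from the most abundant features; see Details).
#' @param frac_inverse_targets fraction of each regulator's targets that are
#'   inversely coupled; the remainder are positively coupled.
#' @param coupling_strength log2 shift of a coupled target's mean per
#'   standard deviation of the regulator's latent log2 expression.
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance mu + phi mu^2).
#' @param mean_log_mu,sd_log_mu natural-log-scale mean and sd of the
#'   log-normal feature means.
#' @param lib_size_factor_range range of the uniform per-sample library
#'   scale factors.
#' @param seed integer master seed; all draws flow from it in a fixed order.
#' @details Regulator miRNAs are always part of the DE set and are planted
#'   among features that are highly expressed in the case group (their
#'   case-group latent mean reaches the 50th-largest baseline mean),
#'   mirroring an analysis design that focuses on the most expressed miRNAs
#'   of the case group.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_mirna = 1546, n_mrna = 5000, n_per_group = 3,
                       frac_de_mirna = 0.15, lfc_de = 2.0,
                       targets_per_mirna = 20, n_regulators = 16,
                       frac_inverse_targets = 0.75, coupling_strength = 1.5,
                       nb_dispersion = 0.1, mean_log_mu = 6.0,
                       sd_log_mu = 1.5, lib_size_factor_range = c(0.7, 1.3),
                       seed = 1) {
  cfg <- list(n_mirna = n_mirna, n_mrna = n_mrna, n_per_group = n_per_group,
              frac_de_mirna = frac_de_mirna, lfc_de = lfc_de,
              targets_per_mirna = targets_per_mirna,
              n_regulators = n_regulators,
              frac_inverse_targets = frac_inverse_targets,
              coupling_strength = coupling_strength,
              nb_dispersion = nb_dispersion, mean_log_mu = mean_log_mu,
              sd_log_mu = sd_log_mu,
              lib_size_factor_range = lib_size_factor_range, seed = seed)
  with(cfg, {
    if (n_mirna < 1 || n_mrna < 1 || n_per_group < 1)
      config_error("feature and sample counts must be positive")
    if (frac_de_mirna < 0 || frac_de_mirna > 1 ||
        frac_inverse_targets < 0 || frac_inverse_targets > 1)
      config_error("fractions must lie in [0, 1]")
    if (targets_per_mirna < 1 || targets_per_mirna > n_mrna)
      config_error("targets_per_mirna must lie in [1, n_mrna]")
    if (n_regulators > round(n_mirna * frac_de_mirna))
      config_error("n_regulators cannot exceed the number of planted DE miRNAs")
    if (nb_dispersion <= 0) config_error("nb_dispersion must be positive")
    if (lfc_de <= 0 || coupling_strength <= 0)
      config_error("lfc_de and coupling_strength must be positive")
    if (length(lib_size_factor_range) != 2L ||
        any(lib_size_factor_range <= 0) ||
        diff(lib_size_factor_range) < 0)
      config_error("lib_size_factor_range must be an increasing positive pair")
  })
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic two-omics dataset
#'
#' Counts are negative binomial with dispersion `nb_dispersion`; feature
#' means are log-normal; per-sample means are
#' `mu_f * lib_s * 2^(g_s * lfc_f)` with `g_s = 1` in the restricted group
#' and `lfc_f` the planted signed log2 fold change (0 for non-DE features).
#' Each regulator miRNA couples its targets through its standardized
#' per-sample latent log2 expression `z_s`: an inversely coupled target's
#' log2 mean is shifted by `-coupling_strength * z_s`, a positively coupled
#' one by `+coupling_strength * z_s`. One master seed drives all draws in a
#' fixed, documented order, so identical configurations give identical
#' output.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with elements `mirna_counts`,
#'   `mrna_counts` (integer matrices), `metadata`, `target_map`
#'   (data.frames), `truth` (list: `de_mirnas` data.frame with signed lfc,
#'   `regulators` character, `regulated_pairs` data.frame with `sign`), and
#'   the resolved `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  S <- 2L * config$n_per_group
  g <- rep(c(0L, 1L), each = config$n_per_group)
  samples <- c(sprintf("control_%d", seq_len(config$n_per_group)),
               sprintf("restricted_%d", seq_len(config$n_per_group)))
  meta <- data.frame(sample = samples,
                     group = rep(c("control", "restricted"),
                                 each = config$n_per_group),
                     stringsAsFactors = FALSE)
  mirna_ids <- sprintf("sim-miR-%04d", seq_len(config$n_mirna))
  gene_ids <- sprintf("gene%05d", seq_len(config$n_mrna))

  # draw order: (1) miRNA means, (2) library factors (miRNA then mRNA),
  # (3) DE set, signs and regulators, (4) mRNA means, (5) target map,
  # (6) coupling assignments, (7) miRNA counts, (8) mRNA counts
  mu_mi <- exp(rnorm(config$n_mirna, config$mean_log_mu, config$sd_log_mu))
  lib_mi <- runif(S, config$lib_size_factor_range[1],
                  config$lib_size_factor_range[2])
  lib_mr <- runif(S, config$lib_size_factor_range[1],
                  config$lib_size_factor_range[2])

  n_de <- round(config$n_mirna * config$frac_de_mirna)
  lfc <- numeric(config$n_mirna)
  reg_idx <- integer(0)
  if (config$n_regulators > 0) {
    # regulators are highly expressed in the case group: a feature is
    # eligible for a signed fold change when its case-group mean (mu shifted
    # by that fold change) reaches the 50th-largest baseline mean. If no
    # feature can support the drawn sign (a 4-fold knockdown from within the
    # top abundance tier needs a very large baseline), the sign is flipped.
    reg_sign <- sample(c(-1, 1), config$n_regulators, replace = TRUE)
    thr <- sort(mu_mi, decreasing = TRUE)[min(50L, config$n_mirna)]
    avail <- rep(TRUE, config$n_mirna)
    reg_idx <- integer(config$n_regulators)
    for (r in seq_len(config$n_regulators)) {
      s <- reg_sign[r]
      elig <- which(avail & mu_mi * 2^(s * config$lfc_de) >= thr)
      if (length(elig) == 0L) {
        s <- -s
        elig <- which(avail & mu_mi * 2^(s * config$lfc_de) >= thr)
      }
      if (length(elig) == 0L) { s <- reg_sign[r]; elig <- which(avail) }
      reg_idx[r] <- if (length(elig) == 1L) elig else sample(elig, 1L)
      avail[reg_idx[r]] <- FALSE
      lfc[reg_idx[r]] <- s * config$lfc_de
    }
    reg_idx <- sort(reg_idx)
  }
  de_idx <- reg_idx
  if (n_de > length(reg_idx)) {
    rest <- setdiff(seq_len(config$n_mirna), reg_idx)
    extra <- sort(sample(rest, n_de - length(reg_idx)))
    lfc[extra] <- sample(c(-1, 1), length(extra), replace = TRUE) * config$lfc_de
    de_idx <- sort(c(reg_idx, extra))
  }

  mu_mr <- exp(rnorm(config$n_mrna, config$mean_log_mu, config$sd_log_mu))

  tgt <- lapply(seq_len(config$n_mirna), function(i)
    sample.int(config$n_mrna, config$targets_per_mirna))
  target_map <- data.frame(
    mirna = rep(mirna_ids, each = config$targets_per_mirna),
    gene = gene_ids[unlist(tgt)], stringsAsFactors = FALSE)

  delta <- matrix(0, nrow = config$n_mrna, ncol = S)  # log2 shifts from coupling
  pair_rows <- list()
  for (r in reg_idx) {
    L <- log2(mu_mi[r]) + g * lfc[r]
    z <- (L - mean(L)) / sd(L)
    k <- config$targets_per_mirna
    n_inv <- round(config$frac_inverse_targets * k)
    inv_pos <- sample.int(k, n_inv)
    sgn <- rep("positive", k); sgn[inv_pos] <- "inverse"
    for (j in seq_len(k)) {
      gi <- tgt[[r]][j]
      delta[gi, ] <- delta[gi, ] +
        (if (sgn[j] == "inverse") -1 else 1) * config$coupling_strength * z
    }
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(mirna = mirna_ids[r], gene = gene_ids[tgt[[r]]], sign = sgn,
                 stringsAsFactors = FALSE)
  }

  mu_mat_mi <- outer(mu_mi, lib_mi) * 2^(outer(lfc, g))
  mirna_counts <- matrix(
    rnbinom(length(mu_mat_mi), mu = mu_mat_mi, size = 1 / config$nb_dispersion),
    nrow = config$n_mirna, dimnames = list(mirna_ids, samples))
  mu_mat_mr <- outer(mu_mr, lib_mr) * 2^delta
  mrna_counts <- matrix(
    rnbinom(length(mu_mat_mr), mu = mu_mat_mr, size = 1 / config$nb_dispersion),
    nrow = config$n_mrna, dimnames = list(gene_ids, samples))

  truth <- list(
    de_mirnas = data.frame(mirna = mirna_ids[de_idx], lfc = lfc[de_idx],
                           stringsAsFactors = FALSE),
    regulators = mirna_ids[reg_idx],
    regulated_pairs = if (length(pair_rows)) do.call(rbind, pair_rows)
                      else data.frame(mirna = character(), gene = character(),
                                      sign = character(),
                                      stringsAsFactors = FALSE))
  structure(list(mirna_counts = mirna_counts, mrna_counts = mrna_counts,
                 metadata = meta, target_map = target_map, truth = truth,
                 config = config),
            class = "sim_dataset")
}

#' Precision and recall of called regulators and pairs
#'
#' `precision = |called && truth| / |called|` (1 when nothing is called, with
#' a logged note) and `recall = |called && truth| / |truth|` (1 when the
#' truth set is empty).
#'
#' @param truth the `truth` element of a [simulate_dataset()] result.
#' @param called_regulators character vector of called regulator miRNAs.
#' @param called_pairs data.frame with columns `mirna`, `gene`, the called
#'   regulator-target pairs.
#' @return data.frame with one row per level (`regulators`, `pairs`) and
#'   columns `n_truth`, `n_called`, `n_hit`, `precision`, `recall`.
#' @export
recovery_report <- function(truth, called_regulators,
                            called_pairs = NULL) {
  pr <- function(truth_keys, called_keys, label) {
    hit <- length(intersect(called_keys, truth_keys))
    if (length(called_keys) == 0L)
      message(sprintf("recovery_report: empty called set for %s; precision 1 by convention", label))
    if (length(truth_keys) == 0L)
      message(sprintf("recovery_report: empty truth set for %s; recall 1 by convention", label))
    data.frame(level = label,
               n_truth = length(truth_keys), n_called = length(called_keys),
               n_hit = hit,
               precision = if (length(called_keys)) hit / length(called_keys) else 1,
               recall = if (length(truth_keys)) hit / length(truth_keys) else 1,
               stringsAsFactors = FALSE)
  }
  pair_key <- function(df) if (is.null(df) || nrow(df) == 0L) character(0)
    else paste(df$mirna, df$gene, sep = "\r")
  truth_pairs <- truth$regulated_pairs
  truth_inv <- truth_pairs[truth_pairs$sign == "inverse", , drop = FALSE]
  out <- pr(unique(truth$regulators), unique(called_regulators), "regulators")
  if (!is.null(called_pairs))
    out <- rbind(out, pr(unique(pair_key(truth_inv)),
                         unique(pair_key(called_pairs)), "pairs"))
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to a directory
#'
#' Emits the four input TSVs (counts, metadata, target map) plus the ground
#' truth (`truth_pairs.tsv`, `truth_de_mirnas.tsv`) and the resolved
#' configuration (`sim_config.yaml`).
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(sim$mirna_counts, file.path(dir, "mirna_counts.tsv"),
                     id_name = "mirna")
  write_count_matrix(sim$mrna_counts, file.path(dir, "mrna_counts.tsv"),
                     id_name = "gene")
  write_results_table(sim$metadata, file.path(dir, "metadata.tsv"))
  write_results_table(sim$target_map, file.path(dir, "target_map.tsv"))
  write_results_table(sim$truth$regulated_pairs,
                      file.path(dir, "truth_pairs.tsv"))
  td <- sim$truth$de_mirnas
  td$regulator <- td$mirna %in% sim$truth$regulators
  write_results_table(td, file.path(dir, "truth_de_mirnas.tsv"))
  cfg <- unclass(sim$config)
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
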