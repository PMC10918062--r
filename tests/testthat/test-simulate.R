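test_that("simulation is seed-deterministic and bookkeeps its truth", {
  cfg <- sim_config(n_mirna = 100, n_mrna = 150, frac_de_mirna = 0.2,
                    n_regulators = 5, targets_per_mirna = 8, seed = 1)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$mirna_counts, s2$mirna_counts)
  expect_identical(s1$mrna_counts, s2$mrna_counts)
  expect_identical(s1$target_map, s2$target_map)
  expect_identical(s1$truth, s2$truth)

  # exactly round(100 * 0.2) = 20 planted DE miRNAs, regulators among them
  expect_identical(nrow(s1$truth$de_mirnas), 20L)
  expect_true(all(s1$truth$regulators %in% s1$truth$de_mirnas$mirna))
  expect_true(all(s1$truth$regulated_pairs$mirna %in% s1$truth$regulators))
  # regulated pairs are a subset of the target map
  key <- function(df) paste(df$mirna, df$gene)
  expect_true(all(key(s1$truth$regulated_pairs) %in% key(s1$target_map)))
  # 75% of each regulator's 8 targets are inverse
  tab <- table(s1$truth$regulated_pairs$mirna,
               s1$truth$regulated_pairs$sign)
  expect_true(all(tab[, "inverse"] == 6))
  validate_count_matrix(s1$mirna_counts)
  validate_count_matrix(s1$mrna_counts)
})

test_that("null configuration plants nothing", {
  s <- simulate_dataset(sim_config(n_mirna = 80, n_mrna = 100,
                                   frac_de_mirna = 0, n_regulators = 0,
                                   targets_per_mirna = 5, seed = 3))
  expect_identical(nrow(s$truth$de_mirnas), 0L)
  expect_length(s$truth$regulators, 0)
  expect_identical(nrow(s$truth$regulated_pairs), 0L)
})

test_that("simulated counts match their negative-binomial moments", {
  # many samples per group, no DE: empirical mean within 3 SE of
  # mu_f x mean library factor, and variance > mean (overdispersion)
  cfg <- sim_config(n_mirna = 400, n_mrna = 10, n_per_group = 100,
                    frac_de_mirna = 0, n_regulators = 0,
                    targets_per_mirna = 2, nb_dispersion = 0.1, seed = 8)
  s <- simulate_dataset(cfg)
  counts <- s$mirna_counts
  # reconstruct the latent means from the seeded draw order
  set.seed(8)
  mu <- exp(rnorm(400, 6, 1.5))
  lib <- runif(200, 0.7, 1.3)
  expected <- mu * mean(lib)
  obs_mean <- rowMeans(counts)
  phi <- 0.1
  se <- sqrt(rowMeans(outer(mu, lib) + phi * outer(mu, lib)^2)) / sqrt(200)
  frac_in <- mean(abs(obs_mean - expected) <= 3 * se)
  expect_gt(frac_in, 0.95)
  # overdispersion: variance exceeds the mean for nearly all features
  obs_var <- apply(counts, 1, var)
  expect_gt(mean(obs_var > obs_mean), 0.9)
})

test_that("inverse coupling yields negative Spearman correlation at n = 50 per group", {
  neg <- 0; total <- 0
  for (seed in 1:20) {
    s <- simulate_dataset(sim_config(n_mirna = 60, n_mrna = 80,
                                     n_per_group = 50, frac_de_mirna = 0.1,
                                     n_regulators = 2, targets_per_mirna = 5,
                                     seed = seed))
    pairs <- s$truth$regulated_pairs
    inv <- pairs[pairs$sign == "inverse", ][1, ]
    rho <- spearman_rho(s$mirna_counts[inv$mirna, ],
                        s$mrna_counts[inv$gene, ])
    total <- total + 1
    neg <- neg + (rho < 0)
  }
  expect_gte(neg / total, 0.95)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(targets_per_mirna = 30, n_mrna = 20),
               class = "mirprop_config_error")
  expect_error(sim_config(n_regulators = 50, n_mirna = 100,
                          frac_de_mirna = 0.1),
               class = "mirprop_config_error")
  expect_error(sim_config(frac_de_mirna = 1.5), class = "mirprop_config_error")
  expect_error(sim_config(nb_dispersion = 0), class = "mirprop_config_error")
})

test_that("recovery reports implement the empty-set conventions", {
  truth <- list(regulators = c("A", "B"),
                regulated_pairs = data.frame(
                  mirna = c("A", "A", "B"), gene = c("g1", "g2", "g3"),
                  sign = c("inverse", "inverse", "positive")))
  r <- recovery_report(truth, c("A", "B"))
  expect_equal(c(r$precision, r$recall), c(1, 1))
  r2 <- recovery_report(truth, c("A", "C"))
  expect_equal(c(r2$precision, r2$recall), c(0.5, 0.5))
  r3 <- suppressMessages(recovery_report(
    list(regulators = character(),
         regulated_pairs = data.frame(mirna = character(), gene = character(),
                                      sign = character())),
    character()))
  expect_equal(c(r3$precision, r3$recall), c(1, 1))
  expect_message(recovery_report(truth, character()), "by convention")
  # pair-level scoring counts only inverse truth pairs
  r4 <- recovery_report(truth, "A",
                        called_pairs = data.frame(mirna = "A", gene = "g1"))
  expect_equal(r4$recall[r4$level == "pairs"], 0.5)
  expect_equal(r4$precision[r4$level == "pairs"], 1)
})

test_that("datasets round-trip through the on-disk artifacts", {
  dir <- withr::local_tempdir()
  s <- simulate_dataset(sim_config(n_mirna = 30, n_mrna = 40,
                                   frac_de_mirna = 0.2, n_regulators = 2,
                                   targets_per_mirna = 4, seed = 5))
  write_dataset(s, dir)
  cm <- read_count_matrix(file.path(dir, "mirna_counts.tsv"))
  expect_identical(unname(cm), unname(s$mirna_counts) * 1.0)
  expect_identical(rownames(cm), rownames(s$mirna_counts))
  tm <- suppressMessages(read_target_map(file.path(dir, "target_map.tsv")))
  expect_identical(nrow(tm), nrow(unique(s$target_map)))
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_identical(meta, s$metadata)
  cfg <- yaml::read_yaml(file.path(dir, "sim_config.yaml"))
  expect_identical(cfg$seed, 5)
})
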