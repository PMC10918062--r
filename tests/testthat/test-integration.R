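test_that("Spearman rho is Pearson on average ranks", {
  expect_equal(spearman_rho(1:3, 3:1), -1)
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(4, 3, 2, 1)), -0.9487,
               tolerance = 1e-4)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(4, 3, 2, 1)),
               cor(c(1, 2, 2, 4), c(4, 3, 2, 1), method = "spearman"))
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)),
               spearman_rho(c(2, 1, 4, 3, 5), 1:5))   # symmetry
  expect_error(spearman_rho(c(1, 1, 1), 1:3), class = "mirprop_degenerate_error")
  expect_error(spearman_rho(1:2, 1:2), class = "mirprop_value_error")
  expect_error(spearman_rho(c(1, 2, NA), 1:3), class = "mirprop_value_error")
})

test_that("exact Spearman p-values equal full permutation enumeration", {
  expect_equal(spearman_pvalue(1, 3, "exact"), 2 / 6)
  expect_equal(spearman_pvalue(0, 5, "exact"), 1)
  expect_equal(spearman_pvalue(0, 20, "t_approx"), 1)

  # oracle: enumerate raw-value permutations and recount, n = 3..6
  # (untied vectors; the enumeration null assumes untied ranks)
  set.seed(42)
  for (n in 3:6) {
    perms <- all_perms(n)
    for (rep_ in 1:4) {
      x <- rnorm(n)
      y <- rnorm(n)
      rho <- cor(rank(x), rank(y))
      oracle <- mean(vapply(perms, function(p)
        abs(cor(rank(x[p]), rank(y))) >= abs(rho) - 1e-12, logical(1)))
      expect_equal(spearman_pvalue(rho, n, "exact"), oracle,
                   tolerance = 1e-12,
                   info = sprintf("n=%d rep=%d", n, rep_))
    }
  }

  # tie-free case agrees with the t approximation only at larger n
  expect_error(spearman_pvalue(1.5, 5), class = "mirprop_value_error")
  expect_error(spearman_pvalue(0.5, 12, "exact"), class = "mirprop_value_error")
})

test_that("one-proportion test uses the continuity-corrected z", {
  r <- one_proportion_test(2, 2)
  expect_equal(r$z, 0.7071, tolerance = 1e-4)
  expect_equal(r$p, 0.4795, tolerance = 1e-4)
  r2 <- one_proportion_test(8, 10)
  expect_equal(r2$z, 1.5811, tolerance = 1e-4)
  expect_equal(r2$p, 0.1138, tolerance = 1e-3)
  # x = n p0 exactly: numerator floored at zero
  r3 <- one_proportion_test(5, 10)
  expect_identical(c(r3$z, r3$p), c(0, 1))
  # exact binomial flag
  r4 <- one_proportion_test(8, 10, method = "exact")
  expect_equal(r4$p, binom.test(8, 10, 0.5)$p.value)
  expect_error(one_proportion_test(3, 0), class = "mirprop_degenerate_error")
  expect_error(one_proportion_test(5, 4), class = "mirprop_value_error")

  # monotone in |x - n p0| beyond the continuity floor
  p_seq <- vapply(5:10, function(x) one_proportion_test(x, 10)$p, numeric(1))
  expect_true(all(diff(p_seq) <= 0))
  # two-sidedness: swapping labels leaves p unchanged
  expect_equal(one_proportion_test(3, 10)$p, one_proportion_test(7, 10)$p)
})

test_that("Clopper-Pearson intervals match printed values and closed forms", {
  expect_equal(round_half_up(clopper_pearson_ci(3, 4), 2),
               c(low = 19.41, high = 99.37))
  expect_equal(round_half_up(clopper_pearson_ci(2, 2), 2),
               c(low = 15.81, high = 100))
  expect_identical(unname(clopper_pearson_ci(0, 5)[1]), 0)
  expect_identical(unname(clopper_pearson_ci(5, 5)[2]), 100)

  # closed forms and reflection symmetry under x -> n - x
  for (n in c(2, 4, 7)) {
    ci_hi <- clopper_pearson_ci(n, n)
    expect_equal(unname(ci_hi[1]), 100 * 0.025^(1 / n), tolerance = 1e-10)
    for (x in 0:n) {
      a <- clopper_pearson_ci(x, n)
      b <- clopper_pearson_ci(n - x, n)
      expect_equal(unname(a), unname(100 - rev(b)), tolerance = 1e-10)
      # the interval always covers the point estimate
      expect_true(a[1] <= 100 * x / n + 1e-9 && a[2] >= 100 * x / n - 1e-9)
    }
  }
  expect_error(clopper_pearson_ci(1, 2, conf = 1.2), class = "mirprop_value_error")
})

test_that("direction calls follow the majority rule", {
  expect_identical(direction_call(3, 1), "YES")
  expect_identical(direction_call(1, 3), "NO")
  expect_identical(direction_call(2, 2), "EQUAL")
  expect_error(direction_call(-1, 0), class = "mirprop_value_error")
})

test_that("correlate_targets applies the significance and presence filters", {
  l2m <- function(m) {
    nm <- new_norm_matrix(m); attr(nm, "log2") <- TRUE; nm
  }
  samples <- paste0("s", 1:6)
  mir <- matrix(c(6, 5, 4, 3, 2, 1), 1, dimnames = list("miR-1", samples))
  gen <- rbind(g_inv = 1:6, g_pos = c(6, 5, 4, 3, 2, 1), g_flat = 1:6)
  colnames(gen) <- samples
  targets <- c("g_inv", "g_pos", "g_flat", "g_absent")

  # no target in the significant set -> zero records
  r0 <- suppressMessages(correlate_targets("miR-1", targets, l2m(mir),
                                           l2m(gen), character(0)))
  expect_identical(nrow(r0), 0L)

  # g_absent is significant but missing from the matrix -> logged exclusion
  expect_message(
    r <- correlate_targets("miR-1", targets, l2m(mir), l2m(gen),
                           c("g_inv", "g_pos", "g_absent")),
    "absent from expression matrix")
  expect_identical(sort(r$gene), c("g_inv", "g_pos"))
  expect_identical(r$cls[r$gene == "g_inv"], "inverse")
  expect_identical(r$cls[r$gene == "g_pos"], "positive")
  expect_equal(r$p, rep(2 / 720, 2))

  bad <- gen; colnames(bad) <- rev(samples)
  expect_error(correlate_targets("miR-1", targets, l2m(mir), l2m(bad),
                                 "g_inv"),
               class = "mirprop_consistency_error")
})

test_that("integrate_mirna assembles proportion tests and candidates", {
  set.seed(9)
  samples <- paste0("s", 1:12)
  l2m <- function(m) { nm <- new_norm_matrix(m); attr(nm, "log2") <- TRUE; nm }
  x <- as.numeric(1:12) + rnorm(12, 0, 0.01)
  mir <- matrix(x, 1, dimnames = list("miR-1", samples))
  # six anticorrelated targets plus one positive target that is kept out of
  # the significant mRNA set (exercises the filter)
  gen <- rbind(t1 = -x, t2 = -x + rnorm(12, 0, 0.1), t3 = -2 * x,
               t4 = rev(x) + rnorm(12, 0, 0.1), t5 = -x^1.1,
               t6 = -x + rnorm(12, 0, 0.2), t7 = x)
  colnames(gen) <- samples
  tmap <- data.frame(mirna = "miR-1", gene = rownames(gen))
  de_mirna <- data.frame(feature = "miR-1", log2fc = 2.5, p = 0.001)
  fit <- integrate_mirna("miR-1", tmap, l2m(mir), l2m(gen), de_mirna,
                         paste0("t", 1:6))
  expect_s3_class(fit, "mirprop")
  row <- fit$proportion
  expect_identical(nrow(row), 1L)
  expect_identical(c(row$n_sig, row$n_inverse, row$n_positive), c(6L, 6L, 0L))
  expect_identical(row$direction, "YES")
  expect_identical(row$fgr_direction, "up")
  expect_equal(row$p, one_proportion_test(6, 6)$p)
  expect_lt(row$p, 0.05)
  expect_equal(c(row$ci_low, row$ci_high),
               unname(clopper_pearson_ci(6, 6)))
  expect_identical(names(fit$candidates), "miR-1")
  expect_identical(sort(fit$candidates[["miR-1"]]), paste0("t", 1:6))

  # below min_targets -> skipped with a log line
  expect_message(
    fit2 <- integrate_mirna("miR-1", tmap, l2m(mir), l2m(gen), de_mirna,
                            "t1", min_targets = 2),
    "fewer than 2")
  expect_identical(fit2$n_tested, 0L)
  expect_error(integrate_mirna("miR-9", tmap, l2m(mir), l2m(gen), de_mirna,
                               rownames(gen)),
               class = "mirprop_consistency_error")
})

test_that("planted inverse coupling is recovered at n_per_group = 10", {
  sim <- suppressMessages(simulate_dataset(
    sim_config(n_mirna = 120, n_mrna = 300, n_per_group = 10,
               frac_de_mirna = 0.2, n_regulators = 6, targets_per_mirna = 12,
               seed = 4)))
  lin_mi <- cpm(sim$mirna_counts, tmm_factors(sim$mirna_counts))
  lin_mr <- cpm(sim$mrna_counts, tmm_factors(sim$mrna_counts))
  l2_mi <- log2_transform(lin_mi); l2_mr <- log2_transform(lin_mr)
  de_mi <- de_ttest(l2_mi, sim$metadata, "control", "restricted")
  de_mr <- de_ttest(l2_mr, sim$metadata, "control", "restricted")
  reg <- sim$truth$regulators[1]
  pair <- sim$truth$regulated_pairs
  inv_genes <- pair$gene[pair$mirna == reg & pair$sign == "inverse"]
  rec <- suppressMessages(correlate_targets(
    reg, pair$gene[pair$mirna == reg], l2_mi, l2_mr,
    de_mr$feature[de_mr$p < 0.05]))
  # at 10 + 10 samples the coupled pairs are overwhelmingly inverse
  expect_gt(sum(rec$cls == "inverse" & rec$gene %in% inv_genes), 0.5 * length(inv_genes))
})
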