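# Synthetic-data generators: determinism, null configurations, depth
# asymmetry, effect-size fidelity, proteome censoring, smFISH structure and
# the planted signature matrix.

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(n_subjects_human = -1), "subject counts")
  expect_error(sim_config(frac_polarized = 1.5), "frac_polarized")
  expect_error(sim_config(basal_depth_factor = 0), "basal_depth_factor")
  expect_error(sim_config(dispersion = -1), "dispersion")
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- sim_config(n_genes = 100, n_subjects_human = 3, seed = 5)
  a <- simulate_lcm_rnaseq(cfg)
  b <- simulate_lcm_rnaseq(cfg)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$truth, b$truth)
  f1 <- simulate_fish_measurements(3, 4, 1.5, 5, 0.3, seed = 9)
  f2 <- simulate_fish_measurements(3, 4, 1.5, 5, 0.3, seed = 9)
  expect_identical(f1, f2)
})

test_that("null configuration has unit expected ratios everywhere", {
  cfg <- sim_config(n_genes = 150, n_subjects_human = 4, frac_polarized = 0,
                    seed = 3)
  sim <- simulate_lcm_rnaseq(cfg)
  expect_true(all(sim$truth$true_log2_ratio == 0))
  expect_true(all(!sim$truth$is_polarized))
})

test_that("basal depth deficit matches the configured factor", {
  cfg <- sim_config(n_genes = 200, n_subjects_human = 10,
                    basal_depth_factor = 0.5, depth_mean = 1e5, seed = 2)
  sim <- simulate_lcm_rnaseq(cfg)
  basal <- sim$counts$meta$compartment == "basal"
  sums <- colSums(sim$counts$values[, basal])
  expect_equal(length(sums), 20L)
  se <- sd(sums) / sqrt(length(sums))
  expect_lt(abs(mean(sums) - 5e4), 3 * se)
})

test_that("polarized genes attain their configured effect size", {
  cfg <- sim_config(n_genes = 250, n_subjects_human = 50,
                    frac_polarized = 0.2, effect_size_log2 = 1.5,
                    depth_mean = 5e4, seed = 8)
  sim <- simulate_lcm_rnaseq(cfg)
  expr <- total_count_normalize(sim$counts)
  fit <- polarization_test(expr, normalization_params(min_mean_expr = 0))
  tab <- merge(fit$table, sim$truth, by = "gene_id")
  pol <- tab$is_polarized
  # mean observed score of polarized genes tracks the signed truth
  err <- tab$score[pol] - tab$true_log2_ratio[pol]
  expect_lt(abs(mean(err)), 0.1)
  expect_lt(abs(mean(tab$score[!pol])), 0.1)
})

test_that("proteome censoring, contaminants and effect sizes behave", {
  cfg <- sim_config(n_genes = 1000, contaminant_frac = 0.05,
                    proteome_detect_floor = 0, seed = 4)
  sim <- simulate_lcm_rnaseq(cfg)
  pr <- simulate_proteome(cfg, sim$truth)
  expect_false(anyNA(pr$proteins$values))            # floor 0 -> no censoring
  expect_equal(sum(pr$proteins$contaminant), 50L)    # exact by construction
  expect_true(any(pr$proteins$unique_peptides < 2))

  cfg2 <- sim_config(n_genes = 300, proteome_detect_floor = 0.3, seed = 4)
  pr2 <- simulate_proteome(cfg2, simulate_lcm_rnaseq(cfg2)$truth)
  expect_true(anyNA(pr2$proteins$values))
  # censoring is left-tailed: missing cells sit at low fitted abundances
  v <- pr2$proteins$values
  expect_lt(min(v, na.rm = TRUE), quantile(v, 0.5, na.rm = TRUE))

  # Monte-Carlo effect recovery over many subjects
  cfg3 <- sim_config(n_genes = 120, frac_polarized = 0.5, effect_size_log2 = 1,
                     n_subjects_proteome = 60, ibaq_noise_sd = 0.5,
                     proteome_detect_floor = 0, contaminant_frac = 0, seed = 6)
  truth3 <- simulate_lcm_rnaseq(cfg3)$truth
  pr3 <- simulate_proteome(cfg3, truth3)
  v3 <- log2(pr3$proteins$values)
  ap <- pr3$proteins$meta$compartment == "apical"
  gap <- rowMeans(v3[, ap]) - rowMeans(v3[, !ap])
  pol <- truth3$is_polarized
  expect_lt(abs(mean(gap[pol] - truth3$true_log2_ratio[pol])), 0.1)
})

test_that("fish measurements honor ratio, background and the noiseless limit", {
  f <- simulate_fish_measurements(6, 40, true_ratio = 1, background = 0,
                                  noise_sd = 0.2, seed = 1)
  r <- log2(f$apical_intensity / f$basal_intensity)
  expect_lt(abs(mean(r)), 0.05)
  fl <- simulate_fish_measurements(2, 10, true_ratio = 2, background = 7,
                                   noise_sd = 1e-9, seed = 2)
  ratio <- (fl$apical_intensity - fl$apical_background) /
           (fl$basal_intensity - fl$basal_background)
  expect_equal(ratio, rep(2, nrow(fl)), tolerance = 1e-6)
  expect_error(simulate_fish_measurements(2, 5, 1, 0, 0), "noise_sd")
  expect_error(simulate_fish_measurements(2, 5, -1, 0, 0.1), "true_ratio")
})

test_that("signature matrix plants exactly the requested specific set", {
  s0 <- simulate_signature_matrix(5, 100, 0, seed = 3)
  expect_equal(sum(enterocyte_specificity(s0$signature)), 0L)
  s <- simulate_signature_matrix(6, 400, 25, seed = 3)
  expect_equal(unname(rowSums(s$signature)), rep(1, 6), tolerance = 1e-12)
  spec <- enterocyte_specificity(s$signature)
  expect_setequal(names(spec)[spec], s$specific_genes)
})

test_that("species pair shares truth with sign-flipped changed genes", {
  cfg <- sim_config(n_genes = 300, frac_polarized = 0.1, seed = 12)
  pair <- simulate_species_pair(cfg, n_changed = 4)
  expect_equal(length(pair$changed_human_ids), 4L)
  ih <- match(pair$changed_human_ids, pair$human$truth$gene_id)
  expect_equal(pair$human$truth$true_log2_ratio[ih],
               -pair$mouse$truth$true_log2_ratio[ih])
  same <- setdiff(seq_len(300), ih)
  expect_equal(pair$human$truth$true_log2_ratio[same],
               pair$mouse$truth$true_log2_ratio[same])
  # species-native identifier styles
  expect_true(all(grepl("^GENE", pair$orthology$human_id)))
  expect_true(all(grepl("^Gene", pair$orthology$mouse_id)))
})
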