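# iBAQ cleaning, imputation, ratios, differential abundance and group tests.

test_that("cleaning removes contaminants, low-peptide rows and shallow samples", {
  set.seed(1)
  vals <- matrix(rlnorm(10 * 8, 10, 1), 10, 8)
  tbl <- build_protein_table(vals,
                             unique_peptides = c(rep(5L, 8), 1L, 1L),
                             contaminant = c(rep(TRUE, 3), rep(FALSE, 7)))
  out <- clean_protein_table(tbl, min_proteins_per_sample = 1)
  expect_equal(nrow(out$values), 5L)  # 10 - 3 contaminants - 2 low-peptide
  expect_true(all(abs(colSums(out$values) - 1) < 1e-9))
  expect_true(out$normalized)
  # order independence of the two row filters
  out2 <- clean_protein_table(tbl, min_proteins_per_sample = 1)
  expect_identical(out$values, out2$values)
})

test_that("degenerate all-equal table errors on normalization", {
  vals <- matrix(5, 4, 8)
  tbl <- build_protein_table(vals)
  expect_error(clean_protein_table(tbl, min_proteins_per_sample = 1),
               "degenerate")
})

test_that("planted shallow samples are exactly the ones dropped", {
  set.seed(2)
  vals <- matrix(rlnorm(200 * 8, 12, 1), 200, 8)
  vals[6:200, c(3, 7)] <- NA  # only 5 proteins detected in two samples
  tbl <- build_protein_table(vals)
  expect_message(out <- clean_protein_table(tbl, min_proteins_per_sample = 100),
                 "low-quality")
  expect_equal(ncol(out$values), 6L)
  expect_false(any(colnames(tbl$values)[c(3, 7)] %in% colnames(out$values)))
})

test_that("imputation is seeded, low and leaves observed values alone", {
  set.seed(3)
  vals <- matrix(rlnorm(300 * 8, 10, 1.5), 300, 8)
  miss <- sample(length(vals), 400)
  vals[miss] <- NA
  tbl <- build_protein_table(vals)
  # no missing -> identity
  full <- build_protein_table(matrix(rlnorm(40, 10, 1), 5, 8))
  expect_identical(impute_missing(full)$values, full$values)
  a <- impute_missing(tbl, seed = 7)
  b <- impute_missing(tbl, seed = 7)
  expect_identical(a$values, b$values)
  expect_false(anyNA(a$values))
  obs <- !is.na(tbl$values)
  expect_identical(a$values[obs], tbl$values[obs])
  # down-shift: imputed median below the observed 5th percentile
  expect_lt(median(a$values[!obs]), quantile(tbl$values[obs], 0.05))
})

test_that("protein log-ratio has its closed forms and antisymmetry", {
  meta <- paired_meta(2, prefix = "P")
  pn <- 1e-6
  vals <- matrix(0, 2, 8, dimnames = list(c("eq", "edge"), meta$sample_id))
  tip_a <- meta$compartment == "apical" & meta$zone == "tip"
  tip_b <- meta$compartment == "basal" & meta$zone == "tip"
  vals["eq", ] <- 0.3
  vals["edge", tip_a] <- pn
  vals["edge", tip_b] <- 0
  tbl <- protein_table(vals, meta, c(5L, 5L), c(FALSE, FALSE))
  lr <- protein_log_ratio(tbl, pn = pn)
  expect_equal(unname(lr["eq"]), 0)
  expect_equal(unname(lr["edge"]), 1)  # log2(2pn/pn)
  # side swap negates
  meta2 <- meta
  meta2$compartment <- ifelse(meta$compartment == "apical", "basal", "apical")
  tbl2 <- protein_table(vals, meta2, c(5L, 5L), c(FALSE, FALSE))
  expect_equal(protein_log_ratio(tbl2, pn = pn), -lr)
})

test_that("differential abundance finds planted fold changes with matching signs", {
  cfg <- sim_config(n_genes = 300, frac_polarized = 0.1, effect_size_log2 = 2,
                    ibaq_noise_sd = 0.25, proteome_detect_floor = 0,
                    contaminant_frac = 0, seed = 40)
  truth <- simulate_lcm_rnaseq(cfg)$truth
  pr <- simulate_proteome(cfg, truth)
  cl <- clean_protein_table(pr$proteins, min_proteins_per_sample = 10)
  da <- differential_abundance(cl)
  tab <- merge(da, truth, by.x = "protein_id", by.y = "gene_id")
  planted <- tab$is_polarized
  expect_true(all(tab$significant[planted]))
  expect_true(all(sign(tab$de_log2fc[planted]) ==
                    sign(tab$true_log2_ratio[planted])))
  # de_log2fc sign concordance with the pn-ratio on significant proteins
  lr <- protein_log_ratio(cl)
  sig <- tab$protein_id[tab$significant]
  agree <- sign(tab$de_log2fc[match(sig, tab$protein_id)]) ==
    sign(lr[sig])
  expect_gte(mean(agree), 0.9)
})

test_that("differential abundance is quiet on null data", {
  cfg <- sim_config(n_genes = 300, frac_polarized = 0, ibaq_noise_sd = 0.3,
                    proteome_detect_floor = 0, contaminant_frac = 0, seed = 41)
  pr <- simulate_proteome(cfg, simulate_lcm_rnaseq(cfg)$truth)
  cl <- clean_protein_table(pr$proteins, min_proteins_per_sample = 10)
  da <- differential_abundance(cl)
  expect_lte(sum(da$significant), 3L)
})

test_that("group polarization test matches enumeration and reports quartiles", {
  set.seed(5)
  ratios <- setNames(c(rep(3, 5) + (1:5) / 50, rep(-3, 20) - (1:20) / 50),
                     paste0("p", 1:25))
  groups <- list(sep = paste0("p", 1:5), tiny = "p9")
  expect_warning(res <- group_polarization_test(ratios, groups), "degenerate")
  expect_equal(res$p_value[res$group == "sep"], 2 / choose(25, 5))
  expect_equal(res$median[res$group == "sep"], median(ratios[1:5]))
  # group drawn from the same distribution is not called
  set.seed(6)
  r2 <- setNames(rnorm(40), paste0("q", 1:40))
  res2 <- group_polarization_test(r2, list(g = paste0("q", 1:10)))
  expect_gt(res2$p_value, 0.05)
  # BH across groups matches the oracle
  r3 <- setNames(c(rnorm(30), rnorm(10, 2)), paste0("r", 1:40))
  res3 <- group_polarization_test(
    r3, list(a = paste0("r", 31:40), b = paste0("r", 1:10), c = paste0("r", 11:20))
  )
  expect_equal(res3$q_value, bh_oracle(res3$p_value))
})

test_that("max-normalization pins the larger side at one", {
  out <- max_normalize(c(4, 0), c(1, 5))
  expect_equal(out$apical_norm, c(1, 0))
  expect_equal(out$basal_norm, c(0.25, 1))
  expect_message(z <- max_normalize(0, 0), "both sides zero")
  expect_equal(unlist(z), c(apical_norm = 0, basal_norm = 0))
  # idempotence
  again <- max_normalize(out$apical_norm, out$basal_norm)
  expect_equal(again, out)
  set.seed(7)
  a <- runif(50); b <- runif(50)
  mn <- max_normalize(a, b)
  expect_true(all(pmax(mn$apical_norm, mn$basal_norm) == 1))
})

test_that("cytoplasmic refilter removes annotated rows and renormalizes", {
  set.seed(8)
  vals <- matrix(rlnorm(50 * 8, 10, 1), 50, 8,
                 dimnames = list(paste0("pr", 1:50), NULL))
  tbl <- build_protein_table(vals)
  cl <- clean_protein_table(tbl, min_proteins_per_sample = 1)
  out <- cytoplasmic_subset(cl, nuclear_only = paste0("pr", 1:3),
                            ecm = paste0("pr", 4:5))
  expect_equal(nrow(out$values), 45L)
  expect_true(all(abs(colSums(out$values) - 1) < 1e-9))
  # no annotations: identity up to renormalization
  out2 <- cytoplasmic_subset(cl, character(), character())
  expect_equal(out2$values, cl$values)
  expect_error(cytoplasmic_subset(cl, paste0("pr", 1:50), character()),
               "no proteins remain")
  # group-test signs for untouched groups survive the refilter
  lr1 <- protein_log_ratio(cl)
  lr2 <- protein_log_ratio(out)
  shared <- intersect(names(lr1), names(lr2))
  expect_gte(cor(lr1[shared], lr2[shared], method = "spearman"), 0.9)
})
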