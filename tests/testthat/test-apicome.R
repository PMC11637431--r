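# Apicome scoring, polarization calling and zonal change detection.

test_that("pseudo-number is the smallest positive entry", {
  m <- matrix(c(0, 0.2, 0.05, 0.75), 2)
  expect_equal(compute_pseudo_number(m), 0.05)
  expect_equal(compute_pseudo_number(matrix(0.1, 2, 2)), 0.1)
  expect_error(compute_pseudo_number(matrix(0, 2, 2)), "no positive")
  sim <- simulate_lcm_rnaseq(sim_config(n_genes = 60, n_subjects_human = 3,
                                        seed = 2))
  e <- total_count_normalize(sim$counts)
  v <- e$values
  expect_equal(compute_pseudo_number(e), min(v[v > 0]))  # exhaustive scan
})

test_that("apicome score has its closed forms and antisymmetry", {
  A <- matrix(runif(12), 3, dimnames = list(NULL, c("s1", "s2", "s3", "s4")))
  pn <- 1e-5
  sc <- apicome_score(A, A, pn)
  expect_equal(unname(sc$score), rep(0, 3))
  # n = 1, A = pn, B = 0 -> log2(2pn/pn) = 1
  expect_equal(unname(apicome_score(matrix(pn), matrix(0), pn)$score), 1)
  # swapping compartments negates the score exactly
  B <- matrix(runif(12), 3, dimnames = dimnames(A))
  expect_equal(apicome_score(A, B, pn)$score, -apicome_score(B, A, pn)$score)
  expect_error(apicome_score(A, B[, c(1, 2)], pn), "dimensions differ")
})

test_that("polarization test calls nothing when compartments are identical", {
  meta <- paired_meta(4)
  set.seed(5)
  profile <- rpois(30, 400) + 1L
  cm <- build_counts(30, meta, function(s) profile)
  fit <- polarization_test(total_count_normalize(cm),
                           normalization_params(min_mean_expr = 0))
  expect_true(all(fit$table$p_value == 1))
  expect_equal(sum(fit$table$polarized), 0L)
  expect_true(all(fit$table$direction == "none"))
})

test_that("genes below the expression floor are not tested", {
  meta <- paired_meta(3)
  set.seed(8)
  cm <- build_counts(20, meta, function(s) {
    v <- rpois(20, 2000) + 1L
    v[1] <- if (s$compartment == "apical") 3L else 0L  # rare but polarized
    v
  })
  fit <- polarization_test(total_count_normalize(cm),
                           normalization_params(min_mean_expr = 1e-3))
  expect_false(rownames(cm$values)[1] %in% fit$table$gene_id)
})

test_that("fewer than two subjects is an error", {
  meta <- paired_meta(1)
  cm <- build_counts(5, meta, function(s) rep(10L, 5))
  expect_error(polarization_test(total_count_normalize(cm)), "2 subjects")
})

test_that("swapping compartment labels negates scores and keeps p-values", {
  sim <- simulate_lcm_rnaseq(sim_config(n_genes = 80, n_subjects_human = 4,
                                        frac_polarized = 0.2, seed = 9))
  e1 <- total_count_normalize(sim$counts)
  meta2 <- sim$counts$meta
  meta2$compartment <- ifelse(meta2$compartment == "apical", "basal", "apical")
  e2 <- total_count_normalize(count_matrix(sim$counts$values, meta2))
  f1 <- polarization_test(e1)
  f2 <- polarization_test(e2)
  expect_equal(f1$table$score, -f2$table$score)
  expect_equal(f1$table$p_value, f2$table$p_value)
})

test_that("scores are invariant to a subject-wide depth rescaling", {
  sim <- simulate_lcm_rnaseq(sim_config(n_genes = 60, n_subjects_human = 4,
                                        seed = 10))
  f1 <- polarization_test(total_count_normalize(sim$counts))
  vals <- sim$counts$values
  s1 <- sim$counts$meta$subject == unique(sim$counts$meta$subject)[1]
  vals[, s1] <- vals[, s1] * 7L
  f2 <- polarization_test(total_count_normalize(count_matrix(vals, sim$counts$meta)),
                          normalization_params(pn = f1$pn))
  expect_equal(f1$table$score, f2$table$score)
  expect_equal(f1$table$p_value, f2$table$p_value)
})

test_that("apicome methods expose the fit", {
  sim <- simulate_lcm_rnaseq(sim_config(n_genes = 50, n_subjects_human = 3,
                                        seed = 3))
  fit <- polarization_test(total_count_normalize(sim$counts))
  expect_s3_class(fit, "apicome")
  expect_output(print(fit), "polarized")
  expect_output(summary(fit), "score quantiles")
  co <- coef(fit)
  expect_named(co)
  expect_equal(length(co), nrow(fit$table))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})

test_that("zonal test is null when tip equals base and finds a planted shift", {
  # identical zones: per-subject tip and base ratios cancel exactly
  meta <- paired_meta(4)
  set.seed(4)
  profile_a <- rpois(25, 300) + 1L
  profile_b <- rpois(25, 300) + 1L
  cm <- build_counts(25, meta, function(s) {
    if (s$compartment == "apical") profile_a else profile_b
  })
  z <- zonal_change_test(total_count_normalize(cm),
                         normalization_params(min_mean_expr = 0))
  expect_true(all(z$p_value == 1))

  # planted zone-shifted gene attains the minimum q
  cfg <- sim_config(n_genes = 200, n_subjects_human = 8, frac_polarized = 0,
                    frac_zonated = 1 / 200, zone_shift_log2 = 2,
                    dispersion = 0.01, seed = 21)
  sim <- simulate_lcm_rnaseq(cfg)
  zz <- zonal_change_test(total_count_normalize(sim$counts))
  planted <- sim$truth$gene_id[sim$truth$is_zonated]
  expect_equal(length(planted), 1L)
  i <- match(planted, zz$gene_id)
  expect_equal(zz$p_value[i], min(zz$p_value))      # unique smallest p
  expect_equal(sum(zz$p_value == zz$p_value[i]), 1L)
  expect_equal(zz$q_value[i], min(zz$q_value))      # attains the minimum q
})

test_that("null polarization p-values are not anticonservative", {
  cfg <- sim_config(n_genes = 1000, n_subjects_human = 8, frac_polarized = 0,
                    seed = 14)
  sim <- simulate_lcm_rnaseq(cfg)
  fit <- polarization_test(total_count_normalize(sim$counts),
                           normalization_params(min_mean_expr = 0))
  # exact test on 8 subjects is discrete; lower tail must not exceed uniform
  frac05 <- mean(fit$table$p_value <= 0.05)
  expect_lt(frac05, 0.05 + 0.02)
  expect_equal(sum(fit$table$polarized), 0L)
})
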