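test_that("haplotype panel generation is deterministic and validated", {
  p1 <- simulate_haplotype_panel(50, 100, rho = 0.8, seed = 5)
  p2 <- simulate_haplotype_panel(50, 100, rho = 0.8, seed = 5)
  expect_identical(p1$alleles, p2$alleles)
  expect_true(all(p1$alleles %in% c(0L, 1L)))
  expect_equal(p1$freqs, colMeans(p1$alleles))
  expect_error(simulate_haplotype_panel(50, 100, maf_range = c(0.4, 0.1)),
               "interval")
  expect_error(simulate_haplotype_panel(50, 100, maf_range = c(0, 0.5)),
               "maf_range")
  expect_error(simulate_haplotype_panel(50, 100, rho = 1), "rho")
})

test_that("rho = 0 gives independent SNPs; marginal frequencies track targets", {
  p <- simulate_haplotype_panel(2, 10000, rho = 0, seed = 9)
  expect_lt(ld_r2(p$alleles[, 1], p$alleles[, 2]), 0.01)
  p1 <- simulate_haplotype_panel(1, 20000, maf_range = c(0.3, 0.3), seed = 10)
  expect_lt(abs(p1$freqs[[1]] - 0.3), 0.02)
})

test_that("ld_r2 matches the haplotype D^2 formula and handles degeneracies", {
  x <- c(0, 1, 1, 0)
  expect_equal(ld_r2(x, x), 1)
  # AB = 40, ab = 40, Ab = 10, aB = 10: D = 0.15, r^2 = 0.36
  v1 <- c(rep(1, 40), rep(0, 40), rep(1, 10), rep(0, 10))
  v2 <- c(rep(1, 40), rep(0, 40), rep(0, 10), rep(1, 10))
  expect_equal(ld_r2(v1, v2), 0.36, tolerance = 1e-12)
  # orthogonal patterns
  expect_equal(ld_r2(c(1, 1, -1, -1), c(1, -1, 1, -1)), 0)
  expect_error(ld_r2(c(1, 1, 1), c(0, 1, 0)), "constant")
  expect_error(ld_r2(1, 1), "length")
})

test_that("scenario_spec enforces hypothesis/index consistency", {
  expect_silent(scenario_spec("H0"))
  expect_error(scenario_spec("H0", causal_disease_idx = 3L), "inconsistent")
  expect_error(scenario_spec("H4", causal_disease_idx = 3L,
                             causal_eqtl_idx = 4L), "inconsistent")
  expect_error(scenario_spec("H3", causal_disease_idx = 3L,
                             causal_eqtl_idx = 3L), "inconsistent")
  expect_silent(scenario_spec("H4_plus_secondary", causal_disease_idx = 3L,
                              causal_eqtl_idx = 3L, secondary_eqtl_idx = 9L))
})

test_that("case-control generator is calibrated under the null", {
  panel <- simulate_haplotype_panel(50, 300, rho = 0.7, seed = 31)
  pvals <- unlist(lapply(1:200, function(i) {
    sc <- scenario_spec("H0", n_cases = 500L, n_controls = 500L,
                        seed = 1000L + i)
    simulate_case_control_gwas(panel, sc)$stats$p
  }))
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("a zero-effect 'causal' SNP reproduces the null generator in law", {
  panel <- simulate_haplotype_panel(30, 200, rho = 0.5, seed = 32)
  sc0 <- scenario_spec("H0", n_cases = 200L, n_controls = 200L, seed = 77L)
  sc1 <- scenario_spec("H1", causal_disease_idx = 5L, log_or = 0,
                       n_cases = 200L, n_controls = 200L, seed = 77L)
  # identical seeds and a zero effect give an identical realisation
  expect_equal(simulate_case_control_gwas(panel, sc0)$stats$p,
               simulate_case_control_gwas(panel, sc1)$stats$p)
})

test_that("the causal SNP attains the minimum p under a strong H1 effect", {
  panel <- simulate_haplotype_panel(50, 400, rho = 0.8, seed = 33)
  idx <- choose_causal_indices(panel, "H1", seed = 34)
  hits <- vapply(1:50, function(i) {
    sc <- scenario_spec("H1", causal_disease_idx = idx$causal_disease_idx,
                        log_or = 0.6, n_cases = 2000L, n_controls = 2000L,
                        seed = 2000L + i)
    st <- simulate_case_control_gwas(panel, sc)$stats
    which.min(st$p) == idx$causal_disease_idx
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("eQTL generator: null decorrelation, slope recovery, determinism", {
  panel <- simulate_haplotype_panel(40, 400, rho = 0.8, seed = 41)
  idx <- choose_causal_indices(panel, "H2", seed = 42)
  k <- idx$causal_eqtl_idx
  # beta_expr = 0: expression uncorrelated with every dosage
  sc0 <- scenario_spec("H2", causal_eqtl_idx = k, beta_expr = 0,
                       n_eqtl1 = 400L, seed = 43L)
  ds0 <- simulate_eqtl_study(panel, sc0, "study1")
  r <- abs(cor(ds0$expression$probe1, ds0$dosages))
  expect_lt(max(r), 0.15)
  # beta_expr = 1 at n = 400: raw-scale OLS recovers the slope
  sc1 <- scenario_spec("H2", causal_eqtl_idx = k, beta_expr = 1,
                       n_eqtl1 = 400L, seed = 44L)
  ds1 <- simulate_eqtl_study(panel, sc1, "study1")
  st <- suppressWarnings(fit_cis_eqtl(ds1, "probe1", standardize = FALSE))
  expect_lt(abs(st$beta[st$snp_id == ds1$snp_ids[k]] - 1), 0.15)
  # determinism and disjoint study sub-seeds
  ds1b <- simulate_eqtl_study(panel, sc1, "study1")
  expect_identical(ds1$expression, ds1b$expression)
  ds2 <- simulate_eqtl_study(panel, sc1, "study2")
  expect_false(identical(ds1$dosages, ds2$dosages))
})

test_that("generator invariants: dosage range, frequency spectrum, H4 truth", {
  panel <- simulate_haplotype_panel(60, 300, rho = 0.9, seed = 51)
  idx <- choose_causal_indices(panel, "H4", seed = 52)
  expect_identical(idx$causal_disease_idx, idx$causal_eqtl_idx)
  sc <- scenario_spec("H4", causal_disease_idx = idx$causal_disease_idx,
                      causal_eqtl_idx = idx$causal_eqtl_idx,
                      n_cases = 300L, n_controls = 300L, n_eqtl1 = 200L,
                      seed = 53L)
  gw <- simulate_case_control_gwas(panel, sc)
  ds <- simulate_eqtl_study(panel, sc, "study1")
  expect_true(all(gw$dosages %in% 0:2))
  expect_true(all(ds$dosages %in% 0:2))
  # genotype allele frequencies track the panel within sampling error
  g_freq <- colMeans(ds$dosages) / 2
  expect_lt(max(abs(g_freq - panel$freqs)), 0.11)
  # H4_plus_secondary picks a secondary SNP in weak LD with the primary
  idx2 <- choose_causal_indices(panel, "H4_plus_secondary", seed = 54)
  r2 <- ld_r2(panel$alleles[, idx2$causal_eqtl_idx],
              panel$alleles[, idx2$secondary_eqtl_idx])
  expect_gt(r2, 0.05)
  expect_lt(r2, 0.7)
})
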