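# Independent oracles and fixture builders shared across tests.

# Brute-force posterior oracle: direct summation over every single-SNP
# causal configuration (i for trait 1, j for trait 2), with per-configuration
# prior weights relative to the null configuration. Natural-scale arithmetic,
# so only valid for moderate Bayes factors and Q.
coloc_enum_oracle <- function(labf1, labf2, priors) {
  Q <- length(labf1)
  bf1 <- exp(labf1); bf2 <- exp(labf2)
  h0 <- 1
  h1 <- priors$p1 * sum(bf1)
  h2 <- priors$p2 * sum(bf2)
  h3 <- 0
  for (i in seq_len(Q)) {
    for (j in seq_len(Q)) {
      if (i != j) h3 <- h3 + bf1[i] * bf2[j]
    }
  }
  h3 <- priors$p1 * priors$p2 * h3
  h4 <- priors$p12 * sum(bf1 * bf2)
  h <- c(h0, h1, h2, h3, h4)
  h / sum(h)
}

# Numerical-integration oracle for the single-SNP Bayes factor: marginal
# likelihood of beta under effect ~ Normal(0, W) versus the point null.
log_abf_integration_oracle <- function(beta, varbeta, W) {
  num <- stats::integrate(
    function(theta) stats::dnorm(beta, theta, sqrt(varbeta)) *
      stats::dnorm(theta, 0, sqrt(W)),
    lower = -Inf, upper = Inf, rel.tol = 1e-12, abs.tol = 0
  )$value
  log(num) - stats::dnorm(beta, 0, sqrt(varbeta), log = TRUE)
}

# Minimal coloc_result stand-in for classification tests.
fake_coloc_result <- function(PP0 = 0, PP1 = 0, PP2 = 0, PP3 = 0, PP4 = 0,
                              Q = 100L) {
  pp <- c(PP0, PP1, PP2, PP3, PP4)
  structure(
    list(Q = Q, PP0 = pp[1], PP1 = pp[2], PP2 = pp[3], PP3 = pp[4],
         PP4 = pp[5], pp3_plus_pp4 = pp[4] + pp[5],
         pp4_over_pp3 = pp[5] / pp[4],
         gwas_min_p = NA_real_, eqtl_min_p = NA_real_,
         classification = NA_character_),
    class = "coloc_result"
  )
}

# Enrichment pairs data.frame realizing a 2x2 table: counts are
# c(candidate successes, candidate failures, other successes, other
# failures); success means PP4 > PP3 with PP3 + PP4 = 0.9 (> 0.8).
pairs_from_counts <- function(counts, cand_gene = "CAND", other_gene = "OTHER") {
  gene <- c(rep(cand_gene, counts[1] + counts[2]),
            rep(other_gene, counts[3] + counts[4]))
  success <- c(rep(TRUE, counts[1]), rep(FALSE, counts[2]),
               rep(TRUE, counts[3]), rep(FALSE, counts[4]))
  data.frame(gene = gene,
             PP3 = ifelse(success, 0.3, 0.6),
             PP4 = ifelse(success, 0.6, 0.3),
             stringsAsFactors = FALSE)
}

# One simulated region under a hypothesis; returns the per-trait log ABF
# vectors over QC'd common SNPs plus minimum p-values and ground truth.
simulate_region_abf <- function(hypothesis, seed, Q = 300L, n_hap = 500L,
                                rho = 0.9, n_cases = 2000L, n_controls = 2000L,
                                n_eqtl = 400L, log_or = 0.5, beta_expr = 1,
                                max_r2_h3 = 0.05) {
  panel <- simulate_haplotype_panel(Q, n_hap, rho = rho, seed = seed)
  idx <- choose_causal_indices(panel, hypothesis, max_r2_h3 = max_r2_h3,
                               seed = seed + 1L)
  sc <- scenario_spec(hypothesis,
                      causal_disease_idx = idx$causal_disease_idx,
                      causal_eqtl_idx = idx$causal_eqtl_idx,
                      secondary_eqtl_idx = idx$secondary_eqtl_idx,
                      log_or = log_or, beta_expr = beta_expr,
                      n_cases = n_cases, n_controls = n_controls,
                      n_eqtl1 = n_eqtl, n_eqtl2 = n_eqtl, seed = seed)
  gw <- simulate_case_control_gwas(panel, sc)
  ds <- simulate_eqtl_study(panel, sc, "study1")
  st <- suppressWarnings(fit_cis_eqtl(ds, "probe1"))
  g <- gw$stats[gw$stats$maf > 0, , drop = FALSE]
  common <- intersect(g$snp_id, st$snp_id)
  g <- g[match(common, g$snp_id), ]
  e <- st[match(common, st$snp_id), ]
  list(
    labf1 = abf_from_pvalue(g$p, g$maf, g$n, "case-control",
                            case_fraction = g$case_fraction[1]),
    labf2 = log_abf(e$beta, e$varbeta, abf_settings()$W_quant),
    gwas_min_p = min(g$p), eqtl_min_p = min(e$p),
    truth = idx, Q = length(common)
  )
}
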