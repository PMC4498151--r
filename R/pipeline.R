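# End-to-end orchestration: synthetic inputs -> QC -> eQTL estimation
# (+ meta-analysis) -> colocalisation per disease x probe x cell state ->
# classification -> enrichment -> calibration curves. Deterministic given
# the config.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    priors = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-6),
    thresholds = list(assoc = 0.8, overlap = 0.99,
                      gwas_gate = 5e-8, eqtl_gate = 1e-10),
    calibration_grid = c(1e-7, 1e-6, 1e-5),
    simulate = list(
      Q = 120L, n_hap = 400L, rho = 0.9, maf_range = c(0.05, 0.5),
      n_cases = 1500L, n_controls = 1500L, n_eqtl1 = 300L, n_eqtl2 = 300L,
      log_or = 0.5, beta_expr = 1,
      diseases = c("disease1", "disease2"),
      cell_states = c("resting", "stimulated"),
      regions = list(
        list(region_id = "r1", hypothesis = "H4", gene = "GENE1",
             candidate = TRUE),
        list(region_id = "r2", hypothesis = "H3", gene = "GENE2",
             candidate = FALSE),
        list(region_id = "r3", hypothesis = "H0", gene = "GENE3",
             candidate = FALSE)
      )
    )
  )
}

load_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.data.frame(config$simulate$regions)) {
      config$simulate$regions <- split(config$simulate$regions,
                                       seq_len(nrow(config$simulate$regions)))
      config$simulate$regions <- lapply(config$simulate$regions, as.list)
    }
  }
  base <- default_pipeline_config()
  merge_cfg <- function(base, user) {
    for (nm in names(user)) {
      base[[nm]] <- if (is.list(user[[nm]]) && !is.null(names(user[[nm]])) &&
                        is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
        merge_cfg(base[[nm]], user[[nm]])
      } else user[[nm]]
    }
    base
  }
  if (is.null(config)) base else merge_cfg(base, config)
}

# SNP QC records derived from an eQTL dosage matrix (call rate, folded MAF,
# HWE z from rounded genotype counts).
snp_records_from_dosages <- function(dosages, snp_info) {
  Q <- ncol(dosages)
  hwe <- numeric(Q); maf <- numeric(Q); call_rate <- numeric(Q)
  for (k in seq_len(Q)) {
    g <- dosages[, k]
    call_rate[k] <- mean(!is.na(g))
    g <- round(g[!is.na(g)])
    maf[k] <- fold_maf(mean(g) / 2)
    hwe[k] <- hwe_zscore(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  data.frame(
    snp_id = snp_info$snp_id, chrom = snp_info$chrom, pos = snp_info$pos,
    allele1 = snp_info$allele1, allele2 = snp_info$allele2,
    maf = maf, call_rate = call_rate, hwe_z = hwe,
    source = "genotyped", info = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Run the full synthetic colocalisation pipeline
#'
#' Validates the configuration (priors first: an invalid `p12 >= p1` aborts
#' before any compute), simulates each configured region (haplotype panel,
#' per-disease case-control GWAS, per-cell-state eQTL cohorts; resting cells
#' combine two studies by fixed-effects meta-analysis), applies SNP QC and
#' region eligibility, runs colocalisation for every disease x probe x
#' cell-state pair, classifies pairs, and produces candidate-gene enrichment
#' and p12 calibration outputs.
#'
#' @param config A config list, a path to a JSON config file, or `NULL` for
#'   the packaged default (3 regions under H4/H3/H0, 2 diseases, 2 cell
#'   states).
#' @param out_dir Optional output directory; when given, writes
#'   `coloc_results.tsv`, `qc_report.tsv`, `enrichment.json`,
#'   `calibration.json` and `truth.json`.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list: `results` (data.frame), `qc` (data.frame of
#'   removed SNPs with reasons), `enrichment`, `calibration`, `truth`,
#'   `config`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, quiet = FALSE) {
  cfg <- load_pipeline_config(config)
  pri <- do.call(coloc_priors, cfg$priors)   # validation before any compute
  grid <- as.numeric(cfg$calibration_grid)
  sim <- cfg$simulate
  say <- function(...) if (!quiet) message(sprintf(...))

  results <- list(); pairs_abf <- list(); qc_removed <- list(); truth <- list()
  for (i in seq_along(sim$regions)) {
    reg <- sim$regions[[i]]
    say("[region %s] simulating panel (Q = %d, rho = %g)",
        reg$region_id, sim$Q, sim$rho)
    panel_seed <- cfg$seed + 1000L * i
    panel <- simulate_haplotype_panel(sim$Q, sim$n_hap,
                                      maf_range = as.numeric(sim$maf_range),
                                      rho = sim$rho, seed = panel_seed)
    idx <- choose_causal_indices(panel, reg$hypothesis, seed = panel_seed + 1L)
    truth[[reg$region_id]] <- c(list(hypothesis = reg$hypothesis,
                                     gene = reg$gene), idx)

    # eQTL cohorts per cell state (shared across diseases).
    eqtl_stats <- list(); eqtl_records <- list()
    for (k in seq_along(sim$cell_states)) {
      state <- sim$cell_states[[k]]
      sc_e <- scenario_spec(reg$hypothesis,
                            causal_disease_idx = idx$causal_disease_idx,
                            causal_eqtl_idx = idx$causal_eqtl_idx,
                            secondary_eqtl_idx = idx$secondary_eqtl_idx,
                            log_or = sim$log_or, beta_expr = sim$beta_expr,
                            n_cases = sim$n_cases, n_controls = sim$n_controls,
                            n_eqtl1 = sim$n_eqtl1, n_eqtl2 = sim$n_eqtl2,
                            seed = panel_seed + 100L * k)
      ds1 <- simulate_eqtl_study(panel, sc_e, "study1", probe_id = reg$gene)
      st1 <- fit_cis_eqtl(ds1, reg$gene)
      if (state == "resting") {
        ds2 <- simulate_eqtl_study(panel, sc_e, "study2", probe_id = reg$gene)
        st2 <- fit_cis_eqtl(ds2, reg$gene)
        eqtl_stats[[state]] <- fixed_effects_meta(st1, st2)
      } else {
        eqtl_stats[[state]] <- st1
      }
      rec <- snp_records_from_dosages(ds1$dosages, panel$snp_info)
      qc <- filter_snps(rec)
      eqtl_records[[state]] <- qc
      if (nrow(qc$removed)) {
        rm_df <- qc$removed[, c("snp_id", "reason")]
        rm_df$region <- reg$region_id; rm_df$cell_state <- state
        qc_removed[[paste(reg$region_id, state)]] <- rm_df
      }
      say("[region %s] %s: %d/%d SNPs pass QC", reg$region_id, state,
          nrow(qc$kept), sim$Q)
    }

    region_spec <- list(region_id = reg$region_id, chrom = "1",
                        start = min(panel$snp_info$pos),
                        end = max(panel$snp_info$pos))
    probe <- data.frame(probe_id = paste0(reg$gene, "_p1"), gene = reg$gene,
                        chrom = "1", start = region_spec$start,
                        end = region_spec$start + 1000L, quality_ok = TRUE,
                        stringsAsFactors = FALSE)

    for (j in seq_along(sim$diseases)) {
      disease <- sim$diseases[[j]]
      sc_d <- scenario_spec(reg$hypothesis,
                            causal_disease_idx = idx$causal_disease_idx,
                            causal_eqtl_idx = idx$causal_eqtl_idx,
                            secondary_eqtl_idx = idx$secondary_eqtl_idx,
                            log_or = sim$log_or, beta_expr = sim$beta_expr,
                            n_cases = sim$n_cases, n_controls = sim$n_controls,
                            n_eqtl1 = sim$n_eqtl1, n_eqtl2 = sim$n_eqtl2,
                            seed = panel_seed + 10L * j)
      gw <- simulate_case_control_gwas(panel, sc_d)
      gstats <- gw$stats[gw$stats$maf > 0 & gw$stats$maf <= 0.5, , drop = FALSE]

      for (state in sim$cell_states) {
        est <- eqtl_stats[[state]]
        kept_ids <- eqtl_records[[state]]$kept$snp_id
        common <- intersect(intersect(gstats$snp_id, est$snp_id), kept_ids)
        elig <- region_eligible(region_spec,
                                cis_window_probes(region_spec, probe),
                                length(common))
        if (!elig$eligible) {
          say("[region %s] %s/%s ineligible: %s", reg$region_id, disease,
              state, paste(elig$reasons, collapse = ","))
          next
        }
        g <- gstats[match(common, gstats$snp_id), ]
        e <- est[match(common, est$snp_id), ]
        labf1 <- abf_from_pvalue(g$p, g$maf, g$n, "case-control",
                                 case_fraction = g$case_fraction[1])
        labf2 <- log_abf(e$beta, e$varbeta, abf_settings()$W_quant)
        res <- coloc_posteriors(
          labf1, labf2, pri, snp_ids = common,
          gwas_min_p = min(g$p), eqtl_min_p = min(e$p),
          meta = list(region = reg$region_id, disease = disease,
                      probe = probe$probe_id, gene = reg$gene,
                      cell_state = state)
        )
        key <- paste(reg$region_id, disease, state, sep = "|")
        results[[key]] <- res
        pairs_abf[[key]] <- list(labf1 = labf1, labf2 = labf2)
        say("[region %s] %s/%s: Q = %d, PP4 = %.3f, class = %s",
            reg$region_id, disease, state, res$Q, res$PP4, res$classification)
      }
    }
  }

  res_df <- coloc_results_table(results)
  candidates <- vapply(sim$regions, function(r) isTRUE(r$candidate), logical(1))
  candidate_genes <- vapply(sim$regions, function(r) r$gene, character(1))[candidates]
  enr <- tryCatch(
    candidate_gene_enrichment(
      data.frame(gene = res_df$gene, PP3 = res_df$PP3, PP4 = res_df$PP4),
      candidate_genes, assoc_threshold = cfg$thresholds$assoc),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "enrichment_table")
  )
  calib <- tryCatch(
    calibrate_p12(coloc_over_grid(pairs_abf, grid, p1 = pri$p1, p2 = pri$p2),
                  grid, threshold = cfg$thresholds$assoc,
                  p1 = pri$p1, p2 = pri$p2),
    error = function(e) list(error = conditionMessage(e))
  )
  qc_df <- if (length(qc_removed)) do.call(rbind, qc_removed) else
    data.frame(snp_id = character(), reason = character(),
               region = character(), cell_state = character())

  out <- list(results = res_df, qc = qc_df, enrichment = enr,
              calibration = calib, truth = truth, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_coloc_table(res_df, file.path(out_dir, "coloc_results.tsv"))
    utils::write.table(qc_df, file.path(out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(enr)[setdiff(names(unclass(enr)), "counts")],
                         file.path(out_dir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    calib_out <- calib
    if (inherits(calib, "calibration_result")) {
      utils::write.table(calib$curves, file.path(out_dir, "calibration_curves.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      calib_out <- unclass(calib)[c("grid", "prior_mean", "posterior_mean",
                                    "n_included", "gap", "chosen_p12",
                                    "inclusion_threshold")]
    }
    jsonlite::write_json(calib_out, file.path(out_dir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
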