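# LD-structured region simulator: haplotype panel, case-control disease
# cohort summarised to p/MAF, and paired eQTL cohorts with per-individual
# dosages and expression. Stands in for controlled-access genotype data so
# every downstream stage is testable.

#' Simulate a haplotype reference panel with Markov LD
#'
#' Haplotypes are binary allele vectors over `Q` SNPs. Each SNP draws a
#' target allele-2 frequency uniformly from `maf_range`. The first SNP is
#' drawn independently per haplotype; SNP `k+1` copies SNP `k`'s allele with
#' probability `rho` and is otherwise redrawn at its own target frequency.
#' This first-order copy process gives one tunable LD-decay parameter with
#' known limits: `rho = 0` yields independent SNPs, `rho -> 1` a single
#' haplotype block.
#'
#' @param Q Number of SNPs (>= 1).
#' @param n_hap Number of haplotypes (>= 2).
#' @param maf_range Interval within (0, 0.5] for target allele frequencies.
#' @param rho Adjacent-SNP copying probability in [0, 1).
#' @param seed Integer seed; the panel is a pure function of the arguments
#'   and the seed.
#' @return An object of class `haplotype_panel`: `Q`, `n_hap`, `alleles`
#'   (n_hap x Q 0/1 matrix), `freqs` (column means), and `snp_info`
#'   (snp_id, chrom, pos, allele1, allele2).
#' @export
simulate_haplotype_panel <- function(Q, n_hap, maf_range = c(0.05, 0.5),
                                     rho = 0.9, seed = 1L) {
  stopifnot_scalar(Q); stopifnot_scalar(n_hap); stopifnot_scalar(rho)
  if (Q < 1) stop("Q must be >= 1")
  if (n_hap < 2) stop("n_hap must be >= 2")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2]) {
    stop("maf_range must be a non-empty interval")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must be contained in (0, 0.5]")
  }
  with_seed(seed, {
    f <- stats::runif(Q, maf_range[1], maf_range[2])
    H <- matrix(0L, nrow = n_hap, ncol = Q)
    H[, 1] <- stats::rbinom(n_hap, 1L, f[1])
    if (Q > 1) {
      for (k in seq_len(Q - 1L)) {
        copy <- stats::runif(n_hap) < rho
        fresh <- stats::rbinom(n_hap, 1L, f[k + 1L])
        H[, k + 1L] <- ifelse(copy, H[, k], fresh)
      }
    }
    snp_info <- data.frame(
      snp_id = sprintf("snp%04d", seq_len(Q)),
      chrom = "1",
      pos = 1000000L + (seq_len(Q) - 1L) * 1000L,
      allele1 = "A",
      allele2 = "G",
      stringsAsFactors = FALSE
    )
    colnames(H) <- snp_info$snp_id
    structure(
      list(Q = as.integer(Q), n_hap = as.integer(n_hap), alleles = H,
           freqs = colMeans(H), target_freqs = f, rho = rho,
           snp_info = snp_info, seed = as.integer(seed)),
      class = "haplotype_panel"
    )
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype panel: %d haplotypes x %d SNPs (rho = %g)\n",
              x$n_hap, x$Q, x$rho))
  invisible(x)
}

#' Causal configuration for one synthetic region
#'
#' Describes the ground truth of a simulated region under one of the five
#' colocalisation hypotheses, plus an `H4_plus_secondary` scenario in which
#' the shared causal variant is accompanied by a second, partially
#' correlated eQTL (emulating primary/secondary eQTL signals in weak LD,
#' r-squared around 0.3).
#'
#' @param hypothesis One of `"H0"`, `"H1"`, `"H2"`, `"H3"`, `"H4"`,
#'   `"H4_plus_secondary"`.
#' @param causal_disease_idx,causal_eqtl_idx,secondary_eqtl_idx SNP column
#'   indices, or `NA` where the hypothesis implies no causal variant.
#' @param log_or Disease log odds ratio per allele at the causal SNP.
#' @param beta_expr Expression effect per allele, in expression-SD units.
#' @param n_cases,n_controls Disease cohort sizes.
#' @param n_eqtl1,n_eqtl2 eQTL cohort sizes.
#' @param seed Master seed; cohorts use fixed sub-seed offsets.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(hypothesis = c("H0", "H1", "H2", "H3", "H4",
                                         "H4_plus_secondary"),
                          causal_disease_idx = NA_integer_,
                          causal_eqtl_idx = NA_integer_,
                          secondary_eqtl_idx = NA_integer_,
                          log_or = 0.5, beta_expr = 1,
                          n_cases = 2000L, n_controls = 2000L,
                          n_eqtl1 = 400L, n_eqtl2 = 400L,
                          seed = 1L) {
  hypothesis <- match.arg(hypothesis)
  d <- causal_disease_idx; e <- causal_eqtl_idx; s <- secondary_eqtl_idx
  ok <- switch(hypothesis,
    H0 = is.na(d) && is.na(e),
    H1 = !is.na(d) && is.na(e),
    H2 = is.na(d) && !is.na(e),
    H3 = !is.na(d) && !is.na(e) && d != e,
    H4 = !is.na(d) && !is.na(e) && d == e,
    H4_plus_secondary = !is.na(d) && !is.na(e) && d == e && !is.na(s) && s != e
  )
  if (!ok) {
    stop(sprintf("causal indices inconsistent with hypothesis %s", hypothesis))
  }
  structure(
    list(hypothesis = hypothesis,
         causal_disease_idx = d, causal_eqtl_idx = e, secondary_eqtl_idx = s,
         log_or = log_or, beta_expr = beta_expr,
         n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         n_eqtl1 = as.integer(n_eqtl1), n_eqtl2 = as.integer(n_eqtl2),
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' Pick causal SNP indices compatible with a hypothesis
#'
#' Convenience helper used by tests and the pipeline: chooses causal indices
#' from a panel so that H3 pairs are nearly uncorrelated (`r^2 <
#' max_r2_h3`) and the secondary eQTL of `H4_plus_secondary` sits near the
#' target LD (`r^2` closest to `target_r2_secondary`).
#'
#' @param panel A `haplotype_panel`.
#' @param hypothesis Scenario hypothesis string.
#' @param max_r2_h3 Upper bound on causal-pair LD under H3.
#' @param target_r2_secondary Target `r^2` between primary and secondary
#'   eQTLs.
#' @param seed Integer seed.
#' @return A named list with `causal_disease_idx`, `causal_eqtl_idx`,
#'   `secondary_eqtl_idx` (NA where unused).
#' @export
choose_causal_indices <- function(panel, hypothesis,
                                  max_r2_h3 = 0.05,
                                  target_r2_secondary = 0.3,
                                  seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  H <- panel$alleles
  usable <- which(panel$freqs > 0.05 & panel$freqs < 0.95)
  if (length(usable) < 2) stop("panel too degenerate to place causal SNPs")
  with_seed(seed, {
    pick <- function() sample(usable, 1L)
    na <- NA_integer_
    switch(hypothesis,
      H0 = list(causal_disease_idx = na, causal_eqtl_idx = na,
                secondary_eqtl_idx = na),
      H1 = list(causal_disease_idx = pick(), causal_eqtl_idx = na,
                secondary_eqtl_idx = na),
      H2 = list(causal_disease_idx = na, causal_eqtl_idx = pick(),
                secondary_eqtl_idx = na),
      H3 = {
        i <- pick()
        r2 <- apply(H[, usable, drop = FALSE], 2,
                    function(v) if (stats::sd(v) == 0) 1 else
                      stats::cor(v, H[, i])^2)
        low <- usable[r2 < max_r2_h3]
        if (length(low) == 0) {
          stop("no SNP pair with r^2 below the H3 bound; increase Q or lower rho")
        }
        list(causal_disease_idx = i,
             causal_eqtl_idx = low[sample.int(length(low), 1L)],
             secondary_eqtl_idx = na)
      },
      H4 = {
        i <- pick()
        list(causal_disease_idx = i, causal_eqtl_idx = i,
             secondary_eqtl_idx = na)
      },
      H4_plus_secondary = {
        i <- pick()
        r2 <- apply(H[, usable, drop = FALSE], 2,
                    function(v) if (stats::sd(v) == 0) 1 else
                      stats::cor(v, H[, i])^2)
        r2[usable == i] <- Inf
        j <- usable[which.min(abs(r2 - target_r2_secondary))]
        list(causal_disease_idx = i, causal_eqtl_idx = i,
             secondary_eqtl_idx = j)
      },
      stop("unknown hypothesis")
    )
  })
}

# Draw n individuals as random haplotype pairs; returns row index pairs.
draw_hap_pairs <- function(panel, n) {
  cbind(sample.int(panel$n_hap, n, replace = TRUE),
        sample.int(panel$n_hap, n, replace = TRUE))
}

# Dosage matrix for given haplotype index pairs.
pairs_to_dosage <- function(panel, idx) {
  panel$alleles[idx[, 1], , drop = FALSE] +
    panel$alleles[idx[, 2], , drop = FALSE]
}

# Logistic intercept giving the requested baseline prevalence when the
# causal genotype follows Hardy-Weinberg at the panel frequency.
solve_intercept <- function(f, log_or, prevalence) {
  gp <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  g <- 0:2
  stats::uniroot(
    function(a) sum(gp * stats::plogis(a + log_or * g)) - prevalence,
    interval = c(-30, 10), tol = 1e-10
  )$root
}

# 1-df allelic score test of case status on dosage, vectorized over SNPs.
score_test_p <- function(G, y) {
  ybar <- mean(y)
  n <- length(y)
  U <- as.numeric(crossprod(G, y - ybar))
  gbar <- colMeans(G)
  V <- ybar * (1 - ybar) * (colSums(G^2) - n * gbar^2)
  stat <- ifelse(V > 0, U^2 / V, 0)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Simulate a case-control GWAS over a panel region
#'
#' Individuals are formed by pairing panel haplotypes. Disease status is
#' logistic with a 10 percent baseline prevalence and per-allele log odds
#' `log_or` at the causal SNP (none under H0/H2). Cases and controls are
#' accumulated by rejection sampling to the requested counts; the per-SNP
#' summary p-value is a 1-df allelic score test and MAF is taken from
#' controls, matching the p/MAF granularity of public GWAS summary files.
#'
#' @param panel A `haplotype_panel`.
#' @param scenario A `scenario_spec`; its disease fields must be consistent
#'   with the hypothesis.
#' @param prevalence Baseline disease prevalence (default 0.1).
#' @param max_batches Bound on resampling batches before giving up.
#' @return A list: `dosages` ((n_cases + n_controls) x Q matrix), `status`
#'   (1 = case), and `stats` (data.frame snp_id, chrom, pos, allele1,
#'   allele2, maf, p, n, trait_type, case_fraction).
#' @export
simulate_case_control_gwas <- function(panel, scenario, prevalence = 0.1,
                                       max_batches = 200L) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(scenario, "scenario_spec"))
  causal <- scenario$causal_disease_idx
  has_effect <- !is.na(causal) && scenario$log_or != 0
  f <- if (!is.na(causal)) panel$freqs[causal] else 0.5
  b <- if (has_effect) scenario$log_or else 0
  a <- solve_intercept(f, b, prevalence)

  n_cases <- scenario$n_cases; n_controls <- scenario$n_controls
  with_seed(scenario$seed + 101L, {
    case_idx <- matrix(0L, 0L, 2L); ctrl_idx <- matrix(0L, 0L, 2L)
    batch <- max(1000L, ceiling(n_cases / prevalence / 4))
    for (iter in seq_len(max_batches)) {
      if (nrow(case_idx) >= n_cases && nrow(ctrl_idx) >= n_controls) break
      idx <- draw_hap_pairs(panel, batch)
      g <- if (!is.na(causal)) {
        panel$alleles[idx[, 1], causal] + panel$alleles[idx[, 2], causal]
      } else rep(0, batch)
      y <- stats::rbinom(batch, 1L, stats::plogis(a + b * g))
      if (nrow(case_idx) < n_cases) {
        case_idx <- rbind(case_idx, idx[y == 1L, , drop = FALSE])
      }
      if (nrow(ctrl_idx) < n_controls) {
        ctrl_idx <- rbind(ctrl_idx, idx[y == 0L, , drop = FALSE])
      }
    }
    if (nrow(case_idx) < n_cases || nrow(ctrl_idx) < n_controls) {
      stop("requested case/control counts unattainable under this scenario")
    }
    idx <- rbind(case_idx[seq_len(n_cases), , drop = FALSE],
                 ctrl_idx[seq_len(n_controls), , drop = FALSE])
    status <- c(rep(1L, n_cases), rep(0L, n_controls))
    G <- pairs_to_dosage(panel, idx)
    p <- score_test_p(G, status)
    maf <- fold_maf(colMeans(G[status == 0L, , drop = FALSE]) / 2)
    stats_df <- data.frame(
      panel$snp_info,
      maf = maf,
      p = p,
      n = n_cases + n_controls,
      trait_type = "case-control",
      case_fraction = n_cases / (n_cases + n_controls),
      stringsAsFactors = FALSE
    )
    list(dosages = G, status = status, stats = stats_df)
  })
}

#' Simulate an eQTL cohort over a panel region
#'
#' Expression for the single simulated probe is `beta_expr *
#' dosage(causal_eqtl_idx)` plus, when configured, a secondary effect at
#' `secondary_eqtl_idx` (half the primary effect size), plus standard normal
#' noise. The two studies use disjoint fixed sub-seeds of the scenario seed
#' so they are independent cohorts drawn from the same panel.
#'
#' @param panel A `haplotype_panel`.
#' @param scenario A `scenario_spec`.
#' @param which `"study1"` or `"study2"`.
#' @param probe_id Label for the simulated expression probe.
#' @return An object of class `eqtl_dataset`: `dosages` (n x Q),
#'   `expression` (named list of per-probe vectors), `sample_ids`,
#'   `snp_ids`, `snp_info`.
#' @export
simulate_eqtl_study <- function(panel, scenario,
                                which = c("study1", "study2"),
                                probe_id = "probe1") {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(scenario, "scenario_spec"))
  which <- match.arg(which)
  n <- if (which == "study1") scenario$n_eqtl1 else scenario$n_eqtl2
  if (n < 10) stop("eQTL cohort size must be >= 10")
  sub_seed <- scenario$seed + if (which == "study1") 1009L else 2003L
  with_seed(sub_seed, {
    idx <- draw_hap_pairs(panel, n)
    G <- pairs_to_dosage(panel, idx)
    mu <- rep(0, n)
    if (!is.na(scenario$causal_eqtl_idx) && scenario$beta_expr != 0) {
      mu <- mu + scenario$beta_expr * G[, scenario$causal_eqtl_idx]
    }
    if (!is.na(scenario$secondary_eqtl_idx) && scenario$beta_expr != 0) {
      mu <- mu + 0.5 * scenario$beta_expr * G[, scenario$secondary_eqtl_idx]
    }
    expr <- mu + stats::rnorm(n)
    sample_ids <- sprintf("%s_s%04d", which, seq_len(n))
    rownames(G) <- sample_ids
    names(expr) <- sample_ids
    eqtl_dataset(G, stats::setNames(list(expr), probe_id),
                 snp_info = panel$snp_info)
  })
}

#' Squared allelic correlation (LD r-squared) between two dosage vectors
#'
#' @param dosages1,dosages2 Equal-length numeric vectors (haplotype 0/1 or
#'   genotype 0..2 scale), neither constant.
#' @return Squared Pearson correlation in [0, 1].
#' @examples
#' ld_r2(c(0, 1, 1, 0), c(0, 1, 1, 0))  # 1
#' @export
ld_r2 <- function(dosages1, dosages2) {
  if (length(dosages1) != length(dosages2) || length(dosages1) < 2) {
    stop("ld_r2: vectors must have equal length >= 2")
  }
  ok <- stats::complete.cases(dosages1, dosages2)
  d1 <- dosages1[ok]; d2 <- dosages2[ok]
  if (length(d1) < 2) stop("ld_r2: fewer than 2 complete pairs")
  if (stats::sd(d1) == 0 || stats::sd(d2) == 0) {
    stop("ld_r2: r^2 undefined for a constant vector")
  }
  stats::cor(d1, d2)^2
}
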