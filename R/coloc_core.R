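#' Per-SNP prior probabilities for colocalisation
#'
#' Container for the prior parameterisation of the five-hypothesis model:
#' `p1` is the prior probability that a given SNP is causal for the disease
#' only, `p2` for expression only, and `p12` for both traits; `p0 = 1 - p1 -
#' p2 - p12` (no causal role) is derived. The four probabilities partition
#' the per-SNP prior and must sum to one.
#'
#' Defaults are the conventional values for dense immune-disease regions:
#' `p1 = p2 = 1e-4` (about 20 expected causal SNPs on a 200K array) and
#' `p12 = 1e-6`, the value selected by empirical calibration (see
#' [calibrate_p12()]). Under these defaults one in
#' `(p1 + p12)/p12 = 101` SNPs causal for a given trait is causal for both.
#'
#' @param p1 Per-SNP prior probability of causality for trait 1 (disease)
#'   only.
#' @param p2 Per-SNP prior for trait 2 (expression) only.
#' @param p12 Per-SNP prior of being causal for both traits. Must satisfy
#'   `0 < p12 < min(p1, p2)`.
#' @return An object of class `coloc_priors`: a list with elements `p0`,
#'   `p1`, `p2`, `p12`.
#' @examples
#' coloc_priors()
#' coloc_priors(p12 = 1e-5)
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-6) {
  stopifnot_scalar(p1); stopifnot_scalar(p2); stopifnot_scalar(p12)
  if (p1 <= 0 || p2 <= 0) stop("p1 and p2 must be positive")
  if (p12 <= 0 || p12 >= min(p1, p2)) {
    stop("p12 must satisfy 0 < p12 < min(p1, p2)")
  }
  if (p1 + p2 + p12 >= 1) stop("p1 + p2 + p12 must be < 1")
  structure(
    list(p0 = 1 - p1 - p2 - p12, p1 = p1, p2 = p2, p12 = p12),
    class = "coloc_priors"
  )
}

#' @export
print.coloc_priors <- function(x, ...) {
  cat(sprintf("coloc priors: p1 = %g, p2 = %g, p12 = %g (p0 = %.8f)\n",
              x$p1, x$p2, x$p12, x$p0))
  invisible(x)
}

#' Prior variance of the effect size for approximate Bayes factors
#'
#' The single-SNP approximate Bayes factor places a Normal(0, W) prior on
#' the true effect. `W_cc` applies to case-control traits (log-odds scale,
#' default sd 0.15) and `W_quant` to quantitative traits standardized to
#' unit variance (default sd 0.2).
#'
#' @param W_quant Prior effect variance for quantitative traits.
#' @param W_cc Prior effect variance (log-odds scale) for case-control
#'   traits.
#' @return An object of class `abf_settings`.
#' @export
abf_settings <- function(W_quant = 0.2^2, W_cc = 0.15^2) {
  stopifnot_scalar(W_quant); stopifnot_scalar(W_cc)
  if (W_quant <= 0 || W_cc <= 0) stop("prior effect variances must be > 0")
  structure(list(W_quant = W_quant, W_cc = W_cc), class = "abf_settings")
}

#' Log approximate Bayes factor for a single SNP
#'
#' Evidence for association versus the point null from an effect estimate
#' and its squared standard error, under a Normal(0, W) prior on the true
#' effect. With shrinkage `r = W/(W + varbeta)` and `z = beta/sqrt(varbeta)`,
#' `log ABF = 0.5 * log(1 - r) + r * z^2 / 2`, which equals the log ratio of
#' the marginal likelihood of `beta` under Normal(0, varbeta + W) to that
#' under Normal(0, varbeta).
#'
#' @param beta Estimated effect(s) per allele-2 dosage.
#' @param varbeta Squared standard error(s); must be > 0.
#' @param W Prior variance of the true effect; must be > 0.
#' @return Numeric vector of log Bayes factors.
#' @examples
#' log_abf(0.3, 0.01, 0.04)  # 0.5*log(0.2) + 3.6
#' @export
log_abf <- function(beta, varbeta, W) {
  if (!all(is.finite(beta)) || !all(is.finite(varbeta)) || !all(is.finite(W))) {
    stop("log_abf: non-finite inputs")
  }
  if (any(varbeta <= 0)) stop("log_abf: varbeta must be > 0")
  if (any(W <= 0)) stop("log_abf: W must be > 0")
  r <- W / (W + varbeta)
  z2 <- beta^2 / varbeta
  0.5 * log1p(-r) + r * z2 / 2
}

#' Log approximate Bayes factor from a p-value, MAF and sample size
#'
#' Reconstructs `|z|` from the two-sided p-value and approximates the
#' sampling variance of the standardized effect as
#' `varbeta = 1 / (2 * n * maf * (1 - maf))` for a quantitative trait, with
#' an additional factor `1 / (case_fraction * (1 - case_fraction))` for a
#' case-control trait. `beta = |z| * sqrt(varbeta)` then feeds [log_abf()]
#' with the trait-appropriate prior variance from `settings`.
#'
#' @param p Two-sided p-value(s) in (0, 1]. Values below 1e-300 are clamped
#'   with a warning (the normal quantile underflows).
#' @param maf Minor allele frequency in (0, 0.5].
#' @param n Total sample size (cases + controls for case-control traits).
#' @param trait_type `"quantitative"` or `"case-control"`.
#' @param case_fraction Proportion of cases, required for case-control.
#' @param settings An [abf_settings()] object.
#' @return Numeric vector of log Bayes factors.
#' @export
abf_from_pvalue <- function(p, maf, n,
                            trait_type = c("quantitative", "case-control"),
                            case_fraction = NULL,
                            settings = abf_settings()) {
  trait_type <- match.arg(trait_type)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (any(n < 2)) stop("n must be >= 2")
  if (any(p < 1e-300)) {
    warning("p-values below 1e-300 clamped to 1e-300")
    p <- pmax(p, 1e-300)
  }
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  varbeta <- 1 / (2 * n * maf * (1 - maf))
  if (trait_type == "case-control") {
    if (is.null(case_fraction) || any(case_fraction <= 0 | case_fraction >= 1)) {
      stop("case_fraction in (0,1) required for case-control traits")
    }
    varbeta <- varbeta / (case_fraction * (1 - case_fraction))
    W <- settings$W_cc
  } else {
    W <- settings$W_quant
  }
  log_abf(z * sqrt(varbeta), varbeta, W)
}

#' Prior probabilities of the five hypotheses for a region of Q SNPs
#'
#' Under the single-causal-variant assumption, a region of `Q` SNPs admits
#' five mutually exclusive hypotheses: no causal variant for either trait
#' (H0), a causal variant for the disease only (H1), for expression only
#' (H2), two distinct causal variants (H3), or one shared causal variant
#' (H4). Their prior probabilities are
#' \deqn{P0 = p0^Q,\quad P1 = Q p0^{Q-1} p1,\quad P2 = Q p0^{Q-1} p2,}
#' \deqn{P3 = Q(Q-1) p0^{Q-2} p1 p2,\quad P4 = Q p0^{Q-1} p12,}
#' so that `P4/P3 = p0 * p12 / ((Q - 1) * p1 * p2)`, which decreases as the
#' region grows: the more SNPs a region holds, the less likely the same one
#' is causal for both traits.
#'
#' @param Q Number of SNPs jointly analysed in the region (>= 1).
#' @param priors A [coloc_priors()] object.
#' @return A list with `P0`..`P4` and `p4_over_p3` (`NaN` when `Q = 1`,
#'   where `P3 = 0`).
#' @export
hypothesis_priors <- function(Q, priors = coloc_priors()) {
  stopifnot_scalar(Q)
  if (Q < 1 || Q != round(Q)) stop("Q must be a positive integer")
  stopifnot(inherits(priors, "coloc_priors"))
  p0 <- priors$p0
  P0 <- p0^Q
  P1 <- Q * p0^(Q - 1) * priors$p1
  P2 <- Q * p0^(Q - 1) * priors$p2
  P3 <- Q * (Q - 1) * p0^(Q - 2) * priors$p1 * priors$p2
  P4 <- Q * p0^(Q - 1) * priors$p12
  list(P0 = P0, P1 = P1, P2 = P2, P3 = P3, P4 = P4,
       p4_over_p3 = if (Q == 1) NaN else P4 / P3)
}

#' Posterior probabilities of the five colocalisation hypotheses
#'
#' Combines per-SNP log approximate Bayes factors for two traits over the
#' same ordered SNP set into posterior probabilities PP0-PP4. The
#' unnormalized hypothesis weights are
#' `h0 = 1`, `h1 = p1 * S1`, `h2 = p2 * S2`,
#' `h3 = p1 * p2 * (S1 * S2 - S12)`, `h4 = p12 * S12`,
#' where `S1 = sum_i BF1_i`, `S2 = sum_j BF2_j` and
#' `S12 = sum_i BF1_i * BF2_i`; all sums are computed in log space
#' (log-sum-exp), since region-scale evidence overflows double precision on
#' the natural scale.
#'
#' @param labf1 Per-SNP log ABFs for trait 1 (disease).
#' @param labf2 Per-SNP log ABFs for trait 2 (expression), same SNP order.
#' @param priors A [coloc_priors()] object.
#' @param snp_ids Optional SNP identifiers; when given for both traits the
#'   sets must match element-wise.
#' @param gwas_min_p,eqtl_min_p Optional per-trait minimum p-values in the
#'   region, carried along as classification gates (see [classify_pair()]).
#' @param meta Optional named list of labels (region, disease, probe, gene,
#'   cell_state) attached to the result.
#' @return An object of class `coloc_result`: `Q`, `PP0`..`PP4`,
#'   `pp3_plus_pp4`, `pp4_over_pp3`, `sum_log_abf1`, `sum_log_abf2`,
#'   `gwas_min_p`, `eqtl_min_p`, `classification` and any `meta` labels.
#' @examples
#' pri <- coloc_priors()
#' r <- coloc_posteriors(c(log(10), 0), c(log(10), 0), pri)
#' r$PP4 / r$PP3  # 505 at the default priors
#' @export
coloc_posteriors <- function(labf1, labf2, priors = coloc_priors(),
                             snp_ids = NULL,
                             gwas_min_p = NA_real_, eqtl_min_p = NA_real_,
                             meta = list()) {
  stopifnot(inherits(priors, "coloc_priors"))
  if (length(labf1) != length(labf2)) {
    stop("coloc_posteriors: per-trait log ABF vectors differ in length ",
         "(mismatched SNP sets)")
  }
  Q <- length(labf1)
  if (Q < 1) stop("coloc_posteriors: need at least one SNP")
  if (!is.null(snp_ids)) {
    if (length(snp_ids) != Q) stop("snp_ids length must equal Q")
  }
  if (!all(is.finite(labf1)) || !all(is.finite(labf2))) {
    stop("coloc_posteriors: non-finite log ABFs")
  }

  ls1 <- logsumexp(labf1)            # log S1
  ls2 <- logsumexp(labf2)            # log S2
  ls12 <- logsumexp(labf1 + labf2)   # log S12
  # S1*S2 - S12 > 0 for Q > 1 (all BFs positive); exactly 0 at Q = 1.
  lh <- c(
    h0 = 0,
    h1 = log(priors$p1) + ls1,
    h2 = log(priors$p2) + ls2,
    h3 = if (Q == 1) -Inf else
      log(priors$p1) + log(priors$p2) + logdiffexp(ls1 + ls2, ls12),
    h4 = log(priors$p12) + ls12
  )
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)

  res <- structure(
    c(list(
      Q = Q,
      PP0 = pp[[1]], PP1 = pp[[2]], PP2 = pp[[3]],
      PP3 = pp[[4]], PP4 = pp[[5]],
      pp3_plus_pp4 = pp[[4]] + pp[[5]],
      pp4_over_pp3 = pp[[5]] / pp[[4]],
      sum_log_abf1 = ls1, sum_log_abf2 = ls2,
      gwas_min_p = gwas_min_p, eqtl_min_p = eqtl_min_p,
      snp_ids = snp_ids
    ), meta),
    class = "coloc_result"
  )
  res$classification <-
    if (is.na(gwas_min_p) || is.na(eqtl_min_p)) NA_character_
    else classify_pair(res, gwas_min_p, eqtl_min_p)
  res
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc result over Q = %d SNPs\n", x$Q))
  cat(sprintf("  PP0..PP4: %s\n",
              paste(sprintf("%.4f", c(x$PP0, x$PP1, x$PP2, x$PP3, x$PP4)),
                    collapse = " ")))
  cat(sprintf("  PP3+PP4 = %.4f, PP4/PP3 = %.3f, class = %s\n",
              x$pp3_plus_pp4, x$pp4_over_pp3,
              x$classification %||% NA_character_))
  invisible(x)
}

#' Classify a disease-probe pair from its colocalisation posteriors
#'
#' Applies the reporting gates and thresholds used for dense immune-disease
#' regions: a pair can only be reported as overlapping/colocalising when the
#' disease signal reaches genome-wide significance (`gwas_min_p <= 5e-8`)
#' and the eQTL is convincing (`eqtl_min_p <= 1e-10`). Gated pairs with
#' `PP3 + PP4 >= 0.99` are "overlaps": `convincing` when `PP4/PP3 > 5`,
#' `suggestive` when `PP4/PP3 > 1`, otherwise `distinct`. Below the overlap
#' bar the pair is `one_trait` when H1 or H2 is the modal hypothesis, else
#' `no_assoc`.
#'
#' @param result A `coloc_result`.
#' @param gwas_min_p Minimum disease association p-value in the region.
#' @param eqtl_min_p Minimum eQTL p-value in the region.
#' @param gwas_gate,eqtl_gate Significance gates (defaults 5e-8, 1e-10).
#' @param overlap_threshold PP3+PP4 threshold for an overlap (default 0.99).
#' @return One of `"no_assoc"`, `"one_trait"`, `"distinct"`,
#'   `"suggestive"`, `"convincing"`.
#' @export
classify_pair <- function(result, gwas_min_p, eqtl_min_p,
                          gwas_gate = 5e-8, eqtl_gate = 1e-10,
                          overlap_threshold = 0.99) {
  stopifnot(inherits(result, "coloc_result"))
  stopifnot_scalar(gwas_min_p); stopifnot_scalar(eqtl_min_p)
  gates_ok <- gwas_min_p <= gwas_gate && eqtl_min_p <= eqtl_gate
  if (gates_ok && result$pp3_plus_pp4 >= overlap_threshold) {
    # PP3 = 0 with PP4 > 0 gives ratio +Inf -> convincing.
    ratio <- result$PP4 / result$PP3
    if (ratio > 5) return("convincing")
    if (ratio > 1) return("suggestive")
    return("distinct")
  }
  pp <- c(result$PP0, result$PP1, result$PP2, result$PP3, result$PP4)
  modal <- which.max(pp)
  if (modal %in% c(2L, 3L)) "one_trait" else "no_assoc"
}

#' @export
as.data.frame.coloc_result <- function(x, ...) {
  data.frame(
    region = x$region %||% NA_character_,
    disease = x$disease %||% NA_character_,
    probe = x$probe %||% NA_character_,
    gene = x$gene %||% NA_character_,
    cell_state = x$cell_state %||% NA_character_,
    Q = x$Q,
    PP0 = x$PP0, PP1 = x$PP1, PP2 = x$PP2, PP3 = x$PP3, PP4 = x$PP4,
    pp3_plus_pp4 = x$pp3_plus_pp4,
    pp4_over_pp3 = x$pp4_over_pp3,
    gwas_min_p = x$gwas_min_p,
    eqtl_min_p = x$eqtl_min_p,
    class = x$classification %||% NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Combine a list of coloc results into one table
#' @param results List of `coloc_result` objects.
#' @return A data.frame, one row per result.
#' @export
coloc_results_table <- function(results) {
  stopifnot(is.list(results))
  if (length(results) == 0L) {
    return(as.data.frame(coloc_posteriors(0, 0))[0, ])
  }
  do.call(rbind, lapply(results, as.data.frame))
}
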