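# SNP, probe and region quality control applied before colocalisation.

#' Signed Hardy-Weinberg equilibrium z-score
#'
#' Computes the 1-df chi-square statistic comparing observed genotype counts
#' with Hardy-Weinberg expectations at the allele frequency estimated from
#' the counts themselves, and returns its signed square root; the sign is
#' positive for heterozygote excess and negative for heterozygote deficit,
#' so the conventional filter |z| <= 4 corresponds to chi-square <= 16.
#'
#' @param nAA,nAB,nBB Genotype counts (total >= 1).
#' @return Signed z-score; 0 by convention when the site is monomorphic.
#' @examples
#' hwe_zscore(25, 50, 25)  # 0: exact HWE
#' hwe_zscore(30, 40, 30)  # -2: het deficit, chi-square 4
#' @export
hwe_zscore <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  if (n < 1) stop("hwe_zscore: total count must be >= 1")
  if (any(c(nAA, nAB, nBB) < 0)) stop("hwe_zscore: negative counts")
  pA <- (2 * nAA + nAB) / (2 * n)
  if (pA == 0 || pA == 1) return(0)
  expected <- n * c(pA^2, 2 * pA * (1 - pA), (1 - pA)^2)
  observed <- c(nAA, nAB, nBB)
  chisq <- sum((observed - expected)^2 / expected)
  sign(nAB - expected[2]) * sqrt(chisq)
}

#' Filter SNP records by the genotyped/imputed QC rules
#'
#' Genotyped SNPs are kept when `maf >= 0.005`, `call_rate >= 0.99` and
#' `|hwe_z| <= 4`. Imputed SNPs are kept when `maf >= 0.005`, `|hwe_z| <= 4`
#' and imputation `info >= 0.3` (call rate does not apply). All boundaries
#' are inclusive as printed. The first failing rule, in the order listed, is
#' recorded as the removal reason.
#'
#' @param records A data.frame of SNP records with columns `snp_id`, `maf`,
#'   `call_rate`, `hwe_z`, `source` (`"genotyped"` or `"imputed"`) and
#'   `info` (required, non-missing, for imputed records).
#' @return An object of class `qc_report`: list with `kept` (data.frame)
#'   and `removed` (data.frame with a `reason` column taking values `MAF`,
#'   `CALL_RATE`, `HWE`, `INFO`). Together they partition the input.
#' @export
filter_snps <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("snp_id", "maf", "call_rate", "hwe_z", "source")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("filter_snps: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(records$source %in% c("genotyped", "imputed"))) {
    stop("filter_snps: source must be 'genotyped' or 'imputed'")
  }
  imputed <- records$source == "imputed"
  if (any(imputed)) {
    if (!"info" %in% names(records) || anyNA(records$info[imputed])) {
      stop("filter_snps: imputed records must carry an imputation info score")
    }
  }
  reason <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    reason[i] <- if (r$maf < 0.005) "MAF"
      else if (r$source == "genotyped" && r$call_rate < 0.99) "CALL_RATE"
      else if (abs(r$hwe_z) > 4) "HWE"
      else if (r$source == "imputed" && r$info < 0.3) "INFO"
      else NA_character_
  }
  keep <- is.na(reason)
  removed <- records[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  structure(list(kept = records[keep, , drop = FALSE], removed = removed),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("SNP QC: %d kept, %d removed\n",
              nrow(x$kept), nrow(x$removed)))
  if (nrow(x$removed)) print(table(x$removed$reason))
  invisible(x)
}

#' Probes within the cis window of a disease region
#'
#' A probe is retained when it lies on the region's chromosome, its quality
#' flag is TRUE, and its closed interval `[start, end]` intersects the
#' region extended by `window` base pairs on each side (closed intervals, so
#' a probe ending exactly `window` bp before the region start is retained).
#'
#' @param region A one-row data.frame or list with `region_id`, `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @param probes Data.frame with `probe_id`, `gene`, `chrom`, `start`,
#'   `end`, `quality_ok`.
#' @param window Flank size in bp (default 200000).
#' @return The retained subset of `probes`.
#' @export
cis_window_probes <- function(region, probes, window = 200000L) {
  stopifnot(is.data.frame(probes))
  if (any(probes$start > probes$end)) stop("probe start > end")
  lo <- region$start - window
  hi <- region$end + window
  keep <- probes$chrom == region$chrom &
    probes$quality_ok &
    probes$end >= lo & probes$start <= hi
  probes[keep, , drop = FALSE]
}

#' Region eligibility for colocalisation analysis
#'
#' A region enters the analysis only when at least one quality-passing probe
#' lies within the cis window and at least 20 QC-passing SNPs are shared
#' between the disease and eQTL datasets.
#'
#' @param region Region record (used for reporting only).
#' @param probes Probes retained by [cis_window_probes()].
#' @param common_snps Count of QC-passing SNPs present in both datasets.
#' @param min_common Minimum shared SNP count (default 20).
#' @return A list with `eligible` (flag) and `reasons` (character vector,
#'   possibly empty, of `NO_PROBES` and/or `TOO_FEW_SNPS`).
#' @export
region_eligible <- function(region, probes, common_snps, min_common = 20L) {
  reasons <- character(0)
  if (nrow(probes) == 0L) reasons <- c(reasons, "NO_PROBES")
  if (common_snps < min_common) reasons <- c(reasons, "TOO_FEW_SNPS")
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Probe-overlap LD filter for colocalising signals
#'
#' Signals whose peak SNP is in LD (r-squared > `threshold`) with any SNP
#' overlapping the expression probe's genomic footprint are excluded, since
#' such signals can reflect an effect of the variant on probe hybridisation
#' rather than on expression.
#'
#' @param peak_snp SNP id of the region's peak association.
#' @param overlap_snps Character vector of probe-overlapping SNP ids (may be
#'   empty, in which case the signal is retained with `max_r2 = 0`).
#' @param dosages Numeric matrix (samples x SNPs) with column names covering
#'   `peak_snp` and `overlap_snps`.
#' @param threshold r-squared exclusion threshold (default 0.6, strict
#'   inequality).
#' @return A list with `excluded` (flag) and `max_r2`.
#' @export
probe_overlap_ld_filter <- function(peak_snp, overlap_snps, dosages,
                                    threshold = 0.6) {
  if (length(overlap_snps) == 0L) {
    return(list(excluded = FALSE, max_r2 = 0))
  }
  stopifnot(is.matrix(dosages))
  missing_ids <- setdiff(c(peak_snp, overlap_snps), colnames(dosages))
  if (length(missing_ids)) {
    stop("probe_overlap_ld_filter: SNPs absent from dosage matrix: ",
         paste(missing_ids, collapse = ", "))
  }
  r2 <- vapply(overlap_snps, function(s) {
    if (identical(s, peak_snp)) 1 else ld_r2(dosages[, peak_snp], dosages[, s])
  }, numeric(1))
  max_r2 <- max(r2)
  list(excluded = max_r2 > threshold, max_r2 = max_r2)
}
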