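# Per-SNP expression effect estimation, response-expression traits, and
# inverse-variance fixed-effects meta-analysis of two cohorts.

#' Construct an eQTL dataset
#'
#' @param dosages Numeric matrix, samples x SNPs, entries in [0, 2] or NA
#'   (missing dosages are kept missing, never imputed).
#' @param expression Named list of per-probe expression vectors, each of
#'   length `nrow(dosages)` (names = sample ids where available).
#' @param sample_ids,snp_ids Optional identifiers; default to the dosage
#'   dimnames.
#' @param snp_info Optional data.frame of SNP annotation (snp_id, chrom,
#'   pos, allele1, allele2).
#' @return An object of class `eqtl_dataset`.
#' @export
eqtl_dataset <- function(dosages, expression, sample_ids = NULL,
                         snp_ids = NULL, snp_info = NULL) {
  stopifnot(is.matrix(dosages), is.list(expression))
  sample_ids <- sample_ids %||% rownames(dosages) %||%
    sprintf("s%04d", seq_len(nrow(dosages)))
  snp_ids <- snp_ids %||% colnames(dosages) %||%
    sprintf("snp%04d", seq_len(ncol(dosages)))
  if (length(sample_ids) != nrow(dosages)) stop("sample_ids length mismatch")
  if (length(snp_ids) != ncol(dosages)) stop("snp_ids length mismatch")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (is.null(names(expression)) || any(names(expression) == "")) {
    stop("expression must be a named list keyed by probe_id")
  }
  for (pid in names(expression)) {
    v <- expression[[pid]]
    if (length(v) != nrow(dosages)) {
      stop(sprintf("expression vector '%s' length differs from sample count", pid))
    }
    if (!all(is.finite(v))) stop(sprintf("expression '%s' must be finite", pid))
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- snp_ids
  structure(list(dosages = dosages, expression = expression,
                 sample_ids = sample_ids, snp_ids = snp_ids,
                 snp_info = snp_info),
            class = "eqtl_dataset")
}

#' @export
print.eqtl_dataset <- function(x, ...) {
  cat(sprintf("eQTL dataset: %d samples x %d SNPs, %d probe(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(x$expression)))
  invisible(x)
}

#' Per-SNP cis-eQTL effects by ordinary least squares
#'
#' The probe's expression vector is standardized to zero mean and unit
#' variance, then regressed on each SNP's dosage (with intercept). Missing
#' dosages are dropped pairwise per SNP. For each SNP the slope `beta`, its
#' squared standard error `varbeta` (residual variance with an n - 2
#' denominator over the dosage sum of squares), and the two-sided t-test
#' p-value are returned. SNPs with constant dosage, or fewer than 3 complete
#' pairs, are skipped with a warning.
#'
#' @param dataset An `eqtl_dataset`.
#' @param probe_id Name of the expression trait to fit.
#' @param standardize Standardize the expression vector before fitting
#'   (default TRUE), putting `beta`/`varbeta` on the unit-variance trait
#'   scale consistent with the p/MAF variance approximation used for the
#'   disease trait. Set FALSE to fit on the raw scale.
#' @return A data.frame with columns `snp_id`, `beta`, `varbeta`, `p`,
#'   `maf`, `n`, `trait_type` (`"quantitative"`), plus allele columns when
#'   `snp_info` is attached to the dataset.
#' @export
fit_cis_eqtl <- function(dataset, probe_id, standardize = TRUE) {
  stopifnot(inherits(dataset, "eqtl_dataset"))
  if (!probe_id %in% names(dataset$expression)) {
    stop(sprintf("unknown probe '%s'", probe_id))
  }
  y_raw <- dataset$expression[[probe_id]]
  s <- stats::sd(y_raw)
  if (s == 0) stop(sprintf("probe '%s' has zero expression variance", probe_id))
  y <- if (standardize) (y_raw - mean(y_raw)) / s else y_raw
  G <- dataset$dosages
  Q <- ncol(G)

  out <- vector("list", Q)
  skipped <- character(0)
  for (k in seq_len(Q)) {
    x <- G[, k]
    ok <- !is.na(x)
    n <- sum(ok)
    if (n < 3) { skipped <- c(skipped, dataset$snp_ids[k]); next }
    xk <- x[ok]; yk <- y[ok]
    sxx <- sum((xk - mean(xk))^2)
    if (sxx == 0) { skipped <- c(skipped, dataset$snp_ids[k]); next }
    beta <- sum((xk - mean(xk)) * (yk - mean(yk))) / sxx
    resid <- (yk - mean(yk)) - beta * (xk - mean(xk))
    s2 <- sum(resid^2) / (n - 2)
    varbeta <- s2 / sxx
    p <- if (varbeta == 0) 0 else
      2 * stats::pt(abs(beta) / sqrt(varbeta), df = n - 2, lower.tail = FALSE)
    out[[k]] <- data.frame(
      snp_id = dataset$snp_ids[k],
      beta = beta, varbeta = varbeta, p = p,
      maf = fold_maf(mean(xk) / 2), n = n,
      trait_type = "quantitative",
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped)) {
    warning("skipped SNP(s) with constant dosage or < 3 complete pairs: ",
            paste(skipped, collapse = ", "))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(snp_id = character(), beta = numeric(),
                      varbeta = numeric(), p = numeric(), maf = numeric(),
                      n = integer(), trait_type = character(),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(dataset$snp_info)) {
    res <- merge(res, dataset$snp_info[, c("snp_id", "allele1", "allele2")],
                 by = "snp_id", sort = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Response-expression trait: stimulated minus baseline
#'
#' Forms, per paired sample, the difference `stimulated - baseline` and
#' standardizes it to unit variance, yielding a derived trait usable in
#' [fit_cis_eqtl()] for mapping response eQTLs (variants that determine the
#' change in expression upon stimulation rather than its level). Only
#' samples present in both vectors (matched by name) are used. Note that no
#' between-condition normalisation beyond simple differencing is applied.
#'
#' @param baseline,stimulated Named numeric vectors of expression, names =
#'   sample ids.
#' @param paired_ids Optional explicit set of sample ids to pair; defaults
#'   to the intersection of the two name sets.
#' @param standardize Standardize the differences to unit variance (default
#'   TRUE). The zero-variance degeneracy check applies either way.
#' @return Named numeric vector of (standardized) differences over the
#'   paired samples.
#' @export
response_expression <- function(baseline, stimulated, paired_ids = NULL,
                                standardize = TRUE) {
  if (is.null(names(baseline)) || is.null(names(stimulated))) {
    stop("baseline and stimulated must be named by sample id")
  }
  ids <- paired_ids %||% intersect(names(baseline), names(stimulated))
  if (length(ids) == 0L) stop("no paired samples between conditions")
  missing_ids <- setdiff(ids, intersect(names(baseline), names(stimulated)))
  if (length(missing_ids)) {
    stop("paired ids absent from one condition: ",
         paste(missing_ids, collapse = ", "))
  }
  d <- stimulated[ids] - baseline[ids]
  s <- stats::sd(d)
  if (is.na(s) || s == 0) {
    stop("degenerate response trait: differences have zero variance")
  }
  if (standardize) (d - mean(d)) / s else d
}

# TRUE when the SNP is strand-ambiguous (A/T or C/G).
is_palindromic <- function(a1, a2) {
  pair <- paste(pmin(toupper(a1), toupper(a2)), pmax(toupper(a1), toupper(a2)))
  pair %in% c("A T", "C G")
}

#' Inverse-variance fixed-effects meta-analysis of two eQTL studies
#'
#' Joins two per-SNP summary tables on `snp_id`, harmonises alleles (the
#' second study's effect is sign-flipped when its allele1/allele2 are
#' swapped relative to the first; strand-ambiguous A/T and C/G SNPs with
#' `maf > 0.4` in either study are dropped as unresolvable), and combines by
#' inverse-variance weights: `beta = (w1 b1 + w2 b2)/(w1 + w2)`, `varbeta =
#' 1/(w1 + w2)` with `w = 1/varbeta`, `n = n1 + n2`, p-value from the
#' combined z statistic. SNP x probe pairs present in only one study are not
#' meta-analysed here; pass the single-study table through unchanged
#' instead.
#'
#' @param stats1,stats2 Data.frames with columns `snp_id`, `beta`,
#'   `varbeta`, `n` (and optionally `maf`, `allele1`, `allele2`, `p`).
#' @return A data.frame of combined statistics over the shared SNPs, in the
#'   SNP order of `stats1`.
#' @export
fixed_effects_meta <- function(stats1, stats2) {
  stopifnot(is.data.frame(stats1), is.data.frame(stats2))
  for (nm in c("snp_id", "beta", "varbeta", "n")) {
    if (!nm %in% names(stats1) || !nm %in% names(stats2)) {
      stop("fixed_effects_meta: both tables need column ", nm)
    }
  }
  shared <- intersect(stats1$snp_id, stats2$snp_id)
  if (length(shared) == 0L) {
    return(data.frame(snp_id = character(), beta = numeric(),
                      varbeta = numeric(), p = numeric(), n = integer(),
                      trait_type = character(), stringsAsFactors = FALSE))
  }
  s1 <- stats1[match(shared, stats1$snp_id), , drop = FALSE]
  s2 <- stats2[match(shared, stats2$snp_id), , drop = FALSE]

  b2 <- s2$beta
  drop <- rep(FALSE, length(shared))
  has_alleles <- all(c("allele1", "allele2") %in% names(s1)) &&
    all(c("allele1", "allele2") %in% names(s2))
  if (has_alleles) {
    same <- toupper(s1$allele1) == toupper(s2$allele1) &
      toupper(s1$allele2) == toupper(s2$allele2)
    swapped <- toupper(s1$allele1) == toupper(s2$allele2) &
      toupper(s1$allele2) == toupper(s2$allele1)
    bad <- !(same | swapped)
    if (any(bad)) {
      stop("fixed_effects_meta: irreconcilable alleles for SNP(s): ",
           paste(shared[bad], collapse = ", "))
    }
    b2[swapped] <- -b2[swapped]
    if ("maf" %in% names(s1) && "maf" %in% names(s2)) {
      ambiguous <- is_palindromic(s1$allele1, s1$allele2) &
        (s1$maf > 0.4 | s2$maf > 0.4)
      drop <- drop | ambiguous
    }
  }

  w1 <- 1 / s1$varbeta
  w2 <- 1 / s2$varbeta
  beta <- (w1 * s1$beta + w2 * b2) / (w1 + w2)
  varbeta <- 1 / (w1 + w2)
  z <- beta / sqrt(varbeta)
  out <- data.frame(
    snp_id = shared,
    beta = beta, varbeta = varbeta,
    p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
    n = s1$n + s2$n,
    trait_type = "quantitative",
    stringsAsFactors = FALSE
  )
  if ("maf" %in% names(s1) && "maf" %in% names(s2)) {
    out$maf <- (s1$n * s1$maf + s2$n * s2$maf) / (s1$n + s2$n)
  }
  if (has_alleles) {
    out$allele1 <- s1$allele1
    out$allele2 <- s1$allele2
  }
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
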