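# Readers/writers for the tabular and VCF formats the pipeline touches.
# Internal coordinates are 1-based inclusive everywhere (the VCF
# convention); BED's 0-based half-open intervals are converted at the
# boundary. Readers reject, with a located error, records that violate the
# type invariants -- no silent coercion.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", what, path))
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        na.strings = c("NA", "")))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing_cols, collapse = ", ")))
  }
  df
}

#' Read disease GWAS summary statistics
#'
#' Tab-delimited with header columns `snp`, `chrom`, `pos`, `a1`, `a2`,
#' `maf`, `p` (optional `beta`, `varbeta` are carried through when present).
#' Every row must satisfy `p` in (0, 1] and `maf` in (0, 0.5]; violations
#' abort with the offending row number, since a p-value of 0 or a
#' monomorphic MAF cannot enter the Bayes-factor computation downstream.
#'
#' @param path File path.
#' @param n_cases,n_controls Cohort sizes (> 0); the case fraction
#'   `n_cases / (n_cases + n_controls)` is attached to every record.
#' @return Data.frame of association records: `snp_id`, `chrom`, `pos`,
#'   `allele1`, `allele2`, `maf`, `p`, `n`, `trait_type` (`"case-control"`),
#'   `case_fraction`.
#' @export
read_gwas_summary <- function(path, n_cases, n_controls) {
  stopifnot_scalar(n_cases); stopifnot_scalar(n_controls)
  if (n_cases <= 0 || n_controls <= 0) {
    stop("n_cases and n_controls must be > 0")
  }
  df <- read_tsv_checked(path, c("snp", "chrom", "pos", "a1", "a2", "maf", "p"),
                         "GWAS summary")
  if (nrow(df) == 0L) {
    return(data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), allele1 = character(),
                      allele2 = character(), maf = numeric(), p = numeric(),
                      n = integer(), trait_type = character(),
                      case_fraction = numeric(), stringsAsFactors = FALSE))
  }
  dup <- duplicated(df$snp)
  if (any(dup)) {
    stop("GWAS summary: duplicate snp id(s): ",
         paste(unique(df$snp[dup]), collapse = ", "))
  }
  bad_p <- which(!is.finite(df$p) | df$p <= 0 | df$p > 1)
  if (length(bad_p)) {
    stop(sprintf("GWAS summary: row %d has p outside (0, 1]", bad_p[1]))
  }
  bad_maf <- which(!is.finite(df$maf) | df$maf <= 0 | df$maf > 0.5)
  if (length(bad_maf)) {
    stop(sprintf("GWAS summary: row %d has maf outside (0, 0.5]", bad_maf[1]))
  }
  out <- data.frame(
    snp_id = as.character(df$snp), chrom = as.character(df$chrom),
    pos = as.integer(df$pos),
    allele1 = as.character(df$a1), allele2 = as.character(df$a2),
    maf = df$maf, p = df$p,
    n = as.integer(n_cases + n_controls),
    trait_type = "case-control",
    case_fraction = n_cases / (n_cases + n_controls),
    stringsAsFactors = FALSE
  )
  for (opt in c("beta", "varbeta")) if (opt %in% names(df)) out[[opt]] <- df[[opt]]
  out
}

#' Read region definitions
#'
#' Two dialects: `bed` (no header; columns chrom, start, end, region_id and
#' optionally disease; 0-based half-open) and `tsv1based` (header columns
#' `region_id`, `chrom`, `start`, `end` and optionally `disease`; 1-based
#' inclusive). Output is always internal 1-based inclusive, so a BED record
#' `(999, 2000)` becomes `(1000, 2000)`.
#'
#' @param path File path.
#' @param dialect `"bed"` or `"tsv1based"`.
#' @return Data.frame with `region_id`, `chrom`, `start`, `end`, `disease`.
#' @export
read_regions <- function(path, dialect = c("bed", "tsv1based")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    df <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
    if (ncol(df) < 4) stop("BED regions: need chrom, start, end, name columns")
    out <- data.frame(
      region_id = as.character(df[[4]]),
      chrom = as.character(df[[1]]),
      start = as.integer(df[[2]]) + 1L,  # 0-based half-open -> 1-based incl.
      end = as.integer(df[[3]]),
      disease = if (ncol(df) >= 5) as.character(df[[5]]) else NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    df <- read_tsv_checked(path, c("region_id", "chrom", "start", "end"),
                           "regions")
    out <- data.frame(
      region_id = as.character(df$region_id),
      chrom = as.character(df$chrom),
      start = as.integer(df$start),
      end = as.integer(df$end),
      disease = if ("disease" %in% names(df)) as.character(df$disease)
                else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  bad <- which(out$start > out$end)
  if (length(bad)) {
    stop(sprintf("regions: record %d has start > end after conversion", bad[1]))
  }
  if (any(!nzchar(out$chrom) | is.na(out$chrom))) stop("regions: empty chrom")
  dup <- duplicated(out$region_id)
  if (any(dup)) {
    stop("regions: duplicate region_id(s): ",
         paste(unique(out$region_id[dup]), collapse = ", "))
  }
  out
}

#' Write region definitions (inverse of [read_regions()])
#' @param regions Data.frame with `region_id`, `chrom`, `start`, `end`,
#'   `disease`.
#' @param path Output path.
#' @param dialect `"bed"` or `"tsv1based"`.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, dialect = c("bed", "tsv1based")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    df <- data.frame(regions$chrom, regions$start - 1L, regions$end,
                     regions$region_id, regions$disease)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    df <- regions[, c("region_id", "chrom", "start", "end", "disease")]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read probe annotations
#'
#' Header columns `probe_id`, `gene`, `chrom`, `start`, `end`, `quality_ok`
#' (logical or 0/1); coordinates are 1-based inclusive, the min/max over a
#' probe's position windows.
#'
#' @param path File path.
#' @return Data.frame of probe records.
#' @export
read_probes <- function(path) {
  df <- read_tsv_checked(
    path, c("probe_id", "gene", "chrom", "start", "end", "quality_ok"),
    "probes")
  out <- data.frame(
    probe_id = as.character(df$probe_id), gene = as.character(df$gene),
    chrom = as.character(df$chrom),
    start = as.integer(df$start), end = as.integer(df$end),
    quality_ok = as.logical(df$quality_ok),
    stringsAsFactors = FALSE
  )
  bad <- which(out$start > out$end)
  if (length(bad)) stop(sprintf("probes: record %d has start > end", bad[1]))
  out
}

# Structural pre-scan so malformed VCF data lines are reported with their
# line number (the VCF parser's own errors do not carry one).
scan_vcf_structure <- function(path) {
  lines <- readLines(path)
  header_at <- grep("^#CHROM\t", lines)
  if (length(header_at) != 1L) stop("VCF: expected exactly one #CHROM header line")
  n_fields <- length(strsplit(lines[header_at], "\t", fixed = TRUE)[[1]])
  if (n_fields < 10L) stop("VCF: no sample columns")
  for (i in seq_along(lines)) {
    if (i <= header_at || !nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != n_fields || is.na(suppressWarnings(as.integer(f[2])))) {
      stop(sprintf("VCF: malformed line %d", i))
    }
  }
  invisible(TRUE)
}

#' Read genotype dosages from a VCF file
#'
#' Prefers the `DS` FORMAT field; otherwise genotypes (`GT`) are converted
#' to dosages by counting copies of allele 2 (ALT). Missing entries are
#' propagated as `NA`, never imputed.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @return Numeric matrix of dosages in [0, 2], samples x SNPs, with sample
#'   ids as row names and variant ids as column names.
#' @export
read_dosages <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  if (!grepl("[.]gz$", path)) scan_vcf_structure(path)
  vcf <- VariantAnnotation::readVcf(path)
  g <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(g)) {
    d <- g$DS
    mode(d) <- "numeric"
  } else if ("GT" %in% names(g)) {
    gt <- g$GT
    d <- apply(gt, c(1, 2), function(s) {
      if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_real_)
      alleles <- strsplit(s, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles == "1")
    })
  } else {
    stop("VCF: neither DS nor GT FORMAT field present")
  }
  d <- t(d)  # samples x SNPs
  if (any(d < 0 | d > 2, na.rm = TRUE)) stop("VCF: dosages outside [0, 2]")
  d
}

#' Write a dosage matrix as a minimal VCF (DS FORMAT field)
#'
#' @param dosages Numeric matrix, samples x SNPs, entries in [0, 2] or NA.
#' @param snp_info Data.frame with `snp_id`, `chrom`, `pos`, `allele1`
#'   (REF), `allele2` (ALT), one row per dosage column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosages_vcf <- function(dosages, snp_info, path) {
  stopifnot(is.matrix(dosages), nrow(snp_info) == ncol(dosages))
  samples <- rownames(dosages) %||% sprintf("s%04d", seq_len(nrow(dosages)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(dosages)), function(k) {
    ds <- dosages[, k]
    ds_str <- ifelse(is.na(ds), ".", format(ds, trim = TRUE, digits = 10))
    paste(c(snp_info$chrom[k], snp_info$pos[k], snp_info$snp_id[k],
            snp_info$allele1[k], snp_info$allele2[k], ".", "PASS", ".",
            "DS", ds_str), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

.coloc_table_cols <- c("region", "disease", "probe", "gene", "cell_state",
                       "Q", "PP0", "PP1", "PP2", "PP3", "PP4",
                       "pp3_plus_pp4", "pp4_over_pp3", "gwas_min_p",
                       "eqtl_min_p", "class")

#' Write colocalisation results as a tab-delimited table
#'
#' One row per disease x probe x cell-state pairwise analysis, with columns
#' region, disease, probe, gene, cell_state, Q, PP0..PP4, PP3+PP4, PP4/PP3
#' and classification. Values survive a write/read round trip to better than
#' 1e-6.
#'
#' @param results List of `coloc_result` objects, or a data.frame as
#'   produced by [coloc_results_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coloc_table <- function(results, path) {
  df <- if (is.data.frame(results)) results else coloc_results_table(results)
  missing_cols <- setdiff(.coloc_table_cols, names(df))
  if (length(missing_cols)) {
    stop("coloc table: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  utils::write.table(df[, .coloc_table_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a colocalisation results table written by [write_coloc_table()]
#' @param path File path.
#' @return Data.frame with the standard result columns.
#' @export
read_coloc_table <- function(path) {
  read_tsv_checked(path, .coloc_table_cols, "coloc table")
}

#' Validate a pipeline input file
#'
#' Runs the corresponding reader and reports success or the reader's located
#' error; backs the `colocus io validate` command.
#'
#' @param path File path.
#' @param kind One of `"gwas"`, `"regions_bed"`, `"regions_tsv"`,
#'   `"probes"`, `"vcf"`, `"coloc_table"`.
#' @param ... Extra arguments passed to the reader (e.g. `n_cases`,
#'   `n_controls` for `"gwas"`).
#' @return `TRUE` invisibly on success; otherwise the reader's error.
#' @export
validate_file <- function(path, kind = c("gwas", "regions_bed", "regions_tsv",
                                         "probes", "vcf", "coloc_table"),
                          ...) {
  kind <- match.arg(kind)
  switch(kind,
    gwas = read_gwas_summary(path, ...),
    regions_bed = read_regions(path, "bed"),
    regions_tsv = read_regions(path, "tsv1based"),
    probes = read_probes(path),
    vcf = read_dosages(path),
    coloc_table = read_coloc_table(path)
  )
  invisible(TRUE)
}
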