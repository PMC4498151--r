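write_gwas_fixture <- function(path, rows) {
  writeLines(c("snp\tchrom\tpos\ta1\ta2\tmaf\tp", rows), path)
}

test_that("read_gwas_summary parses records and attaches the case fraction", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gwas_fixture(f, c(
    "rs1\t15\t1000\tA\tG\t0.25\t1e-6",
    "rs2\t15\t2000\tC\tT\t0.10\t0.2",
    "rs3\t15\t3000\tG\tA\t0.50\t1"
  ))
  # T1D cohort sizes: 6693 cases, 12420 controls
  g <- read_gwas_summary(f, 6693, 12420)
  expect_equal(nrow(g), 3L)
  expect_equal(unique(g$case_fraction), 6693 / 19113)
  expect_equal(g$n, rep(19113L, 3))
  expect_equal(g$trait_type, rep("case-control", 3))
  expect_equal(g$allele1, c("A", "C", "G"))  # alleles preserved byte-exactly
  expect_equal(g$maf, c(0.25, 0.10, 0.50))
})

test_that("read_gwas_summary rejects malformed input with located errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  # header only: empty collection, no error
  write_gwas_fixture(f, character(0))
  expect_equal(nrow(read_gwas_summary(f, 10, 10)), 0L)
  # p = 0 is rejected with the row number (log transform downstream)
  write_gwas_fixture(f, c("rs1\t1\t1\tA\tG\t0.2\t0.5",
                          "rs2\t1\t2\tA\tG\t0.2\t0"))
  expect_error(read_gwas_summary(f, 10, 10), "row 2.*p outside")
  # maf outside (0, 0.5]
  write_gwas_fixture(f, "rs1\t1\t1\tA\tG\t0.7\t0.5")
  expect_error(read_gwas_summary(f, 10, 10), "row 1.*maf outside")
  # duplicate snp ids
  write_gwas_fixture(f, c("rs1\t1\t1\tA\tG\t0.2\t0.5",
                          "rs1\t1\t2\tA\tG\t0.2\t0.5"))
  expect_error(read_gwas_summary(f, 10, 10), "duplicate snp")
  # missing required column is named
  writeLines(c("snp\tchrom\tpos\ta1\ta2\tmaf", "rs1\t1\t1\tA\tG\t0.2"), f)
  expect_error(read_gwas_summary(f, 10, 10), "p")
  expect_error(read_gwas_summary(f, 0, 10), "> 0")
})

test_that("region readers convert BED to 1-based inclusive and round-trip", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr15\t999\t2000\tr1\tT1D", f)
  r <- read_regions(f, "bed")
  expect_equal(r$start, 1000L)
  expect_equal(r$end, 2000L)
  # tsv1based keeps coordinates as-is
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("region_id\tchrom\tstart\tend\tdisease",
               "r1\tchr15\t1000\t2000\tT1D"), f2)
  r2 <- read_regions(f2, "tsv1based")
  expect_equal(r2$start, 1000L)
  expect_equal(r2$end, 2000L)
  expect_equal(r, r2)
  # write -> read round trip is the identity in both dialects
  regions <- data.frame(region_id = c("a", "b"), chrom = c("1", "2"),
                        start = c(100L, 5L), end = c(200L, 5L),
                        disease = c("T1D", "MS"), stringsAsFactors = FALSE)
  for (dialect in c("bed", "tsv1based")) {
    ff <- withr::local_tempfile()
    write_regions(regions, ff, dialect)
    expect_equal(read_regions(ff, dialect), regions, ignore_attr = TRUE)
  }
  # start > end after conversion
  writeLines("chr1\t500\t400\tr9", f)
  expect_error(read_regions(f, "bed"), "start > end")
  # duplicate region ids
  writeLines(c("chr1\t1\t10\tr1", "chr1\t5\t20\tr1"), f)
  expect_error(read_regions(f, "bed"), "duplicate region_id")
})

test_that("VCF dosage round trip preserves ids, values and missingness", {
  dos <- matrix(c(0, 1.73, 2, NA, 0.5, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("sampleA", "sampleB"), NULL))
  info <- data.frame(snp_id = c("rs1", "rs2", "rs3"), chrom = "1",
                     pos = c(100L, 200L, 300L), allele1 = "A", allele2 = "G",
                     stringsAsFactors = FALSE)
  colnames(dos) <- info$snp_id
  f <- withr::local_tempfile(fileext = ".vcf")
  write_dosages_vcf(dos, info, f)
  back <- read_dosages(f)
  expect_equal(dim(back), c(2L, 3L))
  expect_equal(rownames(back), c("sampleA", "sampleB"))
  expect_equal(colnames(back), info$snp_id)
  expect_equal(unname(back), unname(dos), tolerance = 1e-9)
})

test_that("GT genotypes convert to allele-2 counts; malformed lines located", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1",
    "1\t200\trs2\tA\tG\t.\tPASS\t.\tGT\t0/0\t./."
  ), f)
  d <- read_dosages(f)
  expect_equal(unname(d["s1", ]), c(1, 0))
  expect_equal(unname(d["s2", "rs1"]), 2)
  expect_true(is.na(d["s2", "rs2"]))
  # malformed data line (wrong field count) is reported with its line number
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT"
  ), f)
  expect_error(read_dosages(f), "line 3")
})

test_that("coloc result tables round-trip to 1e-6", {
  pri <- coloc_priors()
  # empty collection -> header-only file
  f <- withr::local_tempfile(fileext = ".tsv")
  write_coloc_table(list(), f)
  expect_equal(nrow(read_coloc_table(f)), 0L)
  # one result: PP columns sum to 1
  r1 <- coloc_posteriors(log(c(3, 1)), log(c(2, 5)), pri,
                         gwas_min_p = 1e-9, eqtl_min_p = 1e-12,
                         meta = list(region = "r1", disease = "T1D",
                                     probe = "p1", gene = "G1",
                                     cell_state = "monocyte"))
  write_coloc_table(list(r1), f)
  tab <- read_coloc_table(f)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$PP0 + tab$PP1 + tab$PP2 + tab$PP3 + tab$PP4, 1,
               tolerance = 1e-6)
  # ten synthetic results round-trip within 1e-6
  set.seed(81)
  results <- lapply(1:10, function(i) {
    Q <- sample(2:30, 1)
    coloc_posteriors(rnorm(Q, 1, 2), rnorm(Q, 1, 2), pri,
                     gwas_min_p = runif(1), eqtl_min_p = runif(1),
                     meta = list(region = paste0("r", i), disease = "D",
                                 probe = "p", gene = "G", cell_state = "c"))
  })
  write_coloc_table(results, f)
  tab <- read_coloc_table(f)
  orig <- coloc_results_table(results)
  for (col in c("PP0", "PP1", "PP2", "PP3", "PP4", "pp3_plus_pp4",
                "gwas_min_p", "eqtl_min_p")) {
    expect_equal(tab[[col]], orig[[col]], tolerance = 1e-6, label = col)
  }
  expect_error(write_coloc_table(data.frame(x = 1), f), "missing column")
})

test_that("validate_file dispatches to the located readers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gwas_fixture(f, "rs1\t1\t1\tA\tG\t0.2\t0.5")
  expect_true(validate_file(f, "gwas", n_cases = 10, n_controls = 10))
  writeLines(c("probe_id\tgene\tchrom\tstart\tend\tquality_ok",
               "p1\tG1\t1\t100\t200\tTRUE"), f)
  expect_true(validate_file(f, "probes"))
  writeLines(c("probe_id\tgene\tchrom\tstart\tend\tquality_ok",
               "p1\tG1\t1\t300\t200\tTRUE"), f)
  expect_error(validate_file(f, "probes"), "start > end")
})
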