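# Candidate-gene enrichment and classification count summaries.

#' Candidate-gene enrichment among colocalising pairs
#'
#' Restricts to probe/disease pairs with evidence of association with both
#' traits (`PP3 + PP4 > assoc_threshold`), cross-classifies candidate-gene
#' membership against whether the pair gives greater posterior support to a
#' shared causal variant (`PP4 > PP3`), and reports per-stratum odds
#' (successes/failures), their ratio, and a two-sided Fisher exact p-value
#' on the 2x2 counts. Because published tables round odds to three decimals,
#' the ratio of the rounded odds (`odds_ratio_printed`) is reported
#' alongside the raw-count odds ratio.
#'
#' @param pairs Data.frame with columns `gene`, `PP3`, `PP4` (one row per
#'   probe/disease/cell-state pairwise analysis).
#' @param candidates Character vector of candidate causal gene names (may be
#'   empty).
#' @param assoc_threshold Inclusion threshold on `PP3 + PP4` (default 0.8).
#' @return An object of class `enrichment_table`: `n_candidate_pairs`,
#'   `odds_candidate`, `n_other_pairs`, `odds_other`, `odds_ratio`,
#'   `odds_ratio_printed`, `fisher_p`, and the underlying `counts` matrix.
#' @export
candidate_gene_enrichment <- function(pairs, candidates,
                                      assoc_threshold = 0.8) {
  stopifnot(is.data.frame(pairs))
  for (nm in c("gene", "PP3", "PP4")) {
    if (!nm %in% names(pairs)) stop("pairs must have column ", nm)
  }
  keep <- pairs$PP3 + pairs$PP4 > assoc_threshold
  pairs <- pairs[keep, , drop = FALSE]
  in_cand <- pairs$gene %in% candidates
  if (!any(in_cand) || all(in_cand)) {
    stop("candidate_gene_enrichment: empty stratum (all or no pairs in the ",
         "candidate set after thresholding)")
  }
  success <- pairs$PP4 > pairs$PP3
  counts <- matrix(
    c(sum(in_cand & success), sum(in_cand & !success),
      sum(!in_cand & success), sum(!in_cand & !success)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("candidate", "other"), c("PP4>PP3", "PP4<=PP3"))
  )
  odds <- function(s, f) {
    if (f == 0) { warning("zero failures in a stratum: infinite odds"); Inf }
    else s / f
  }
  odds_c <- odds(counts[1, 1], counts[1, 2])
  odds_o <- odds(counts[2, 1], counts[2, 2])
  structure(
    list(
      n_candidate_pairs = sum(in_cand),
      odds_candidate = odds_c,
      n_other_pairs = sum(!in_cand),
      odds_other = odds_o,
      odds_ratio = odds_c / odds_o,
      odds_ratio_printed = round(odds_c, 3) / round(odds_o, 3),
      fisher_p = stats::fisher.test(counts)$p.value,
      counts = counts
    ),
    class = "enrichment_table"
  )
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf(
    "enrichment: candidate %d pairs (odds %.3f) vs other %d pairs (odds %.3f)\n",
    x$n_candidate_pairs, x$odds_candidate, x$n_other_pairs, x$odds_other))
  cat(sprintf("  odds ratio %.3f (ratio of printed odds %.3f), Fisher p = %.3g\n",
              x$odds_ratio, x$odds_ratio_printed, x$fisher_p))
  invisible(x)
}

.class_levels <- c("no_assoc", "one_trait", "distinct", "suggestive",
                   "convincing")

#' Per-disease gene counts of classification categories
#'
#' Counts genes (not pairwise analyses) per disease in the nested
#' categories: overlaps (`PP3 + PP4` above the overlap bar, i.e. class
#' `distinct`, `suggestive` or `convincing`), suggestive (`PP4/PP3 > 1`:
#' class `suggestive` or `convincing`) and convincing. A gene analysed
#' through several probes or cell states is counted once per disease at its
#' maximum-evidence classification; an `at_least_one_disease` row counts
#' each gene once at its maximum over diseases.
#'
#' @param results Data.frame with columns `disease`, `gene`, `class` (values
#'   among `no_assoc`, `one_trait`, `distinct`, `suggestive`,
#'   `convincing`).
#' @return Data.frame with columns `disease`, `overlaps`, `suggestive`,
#'   `convincing`, including the `at_least_one_disease` row.
#' @export
summarize_counts <- function(results) {
  stopifnot(is.data.frame(results))
  for (nm in c("disease", "gene", "class")) {
    if (!nm %in% names(results)) stop("results must have column ", nm)
  }
  if (nrow(results) == 0L) {
    return(data.frame(disease = "at_least_one_disease", overlaps = 0L,
                      suggestive = 0L, convincing = 0L,
                      stringsAsFactors = FALSE))
  }
  bad <- setdiff(unique(results$class), .class_levels)
  if (length(bad)) stop("unknown class value(s): ", paste(bad, collapse = ", "))
  lev <- function(x) match(x, .class_levels)

  count_block <- function(df, label) {
    best <- tapply(lev(df$class), df$gene, max)
    data.frame(
      disease = label,
      overlaps = sum(best >= 3L),
      suggestive = sum(best >= 4L),
      convincing = sum(best >= 5L),
      stringsAsFactors = FALSE
    )
  }
  per_disease <- do.call(rbind, lapply(
    split(results, results$disease),
    function(df) count_block(df, df$disease[1])
  ))
  out <- rbind(per_disease, count_block(results, "at_least_one_disease"))
  rownames(out) <- NULL
  out
}
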