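Package: colocus
Title: Bayesian Colocalisation of GWAS and eQTL Signals with Empirical
    Prior Calibration
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-region Bayesian colocalisation of disease GWAS and
    cis-eQTL association signals under the single-causal-variant
    assumption: approximate Bayes factors from summary statistics
    (effect/standard-error or p-value/MAF/sample-size inputs),
    five-hypothesis posterior probabilities PP0-PP4, empirical
    calibration of the shared-causal-variant prior p12, cis-eQTL
    estimation with inverse-variance fixed-effects meta-analysis of two
    cohorts, SNP/probe/region quality-control filters, classification of
    disease-probe pairs, and candidate-gene enrichment. Ships an
    LD-structured synthetic-data generator (haplotype panel, case-control
    cohort, paired eQTL cohorts) so the whole pipeline is testable
    without access to controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
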