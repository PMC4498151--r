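---
title: "Methods: Bayesian colocalisation of GWAS and eQTL signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian colocalisation of GWAS and eQTL signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colocus)
```

## The model

For a genomic region containing $Q$ SNPs, densely genotyped or well imputed,
we ask whether a disease association signal and a *cis* eQTL signal are
consistent with a single shared causal variant. Under the assumption that at
most one SNP per trait is causal in the region, five mutually exclusive
hypotheses exhaust the possibilities:

* $H_0$: no causal variant for either trait;
* $H_1$: a causal variant for the disease only;
* $H_2$: a causal variant for gene expression only;
* $H_3$: two distinct causal variants, one per trait;
* $H_4$: one causal variant shared by both traits.

Each SNP carries per-SNP prior probabilities $p_1$, $p_2$, $p_{12}$ of being
causal for the disease only, expression only, or both ($p_0$ is the
remainder). Assuming causality is independent across SNPs given the
at-most-one-causal-variant condition, the hypothesis priors are

$$P_0 = p_0^Q,\qquad P_1 = Q\,p_0^{Q-1}p_1,\qquad P_2 = Q\,p_0^{Q-1}p_2,$$
$$P_3 = Q(Q-1)\,p_0^{Q-2}p_1 p_2,\qquad P_4 = Q\,p_0^{Q-1}p_{12},$$

so $P_4/P_3 = p_0\,p_{12}/\big((Q-1)p_1p_2\big)$: the prior odds of
colocalisation fall as the region grows, because any of $Q$ SNPs may be
causal for each trait but only $Q$ of the $Q^2$ ordered pairs are shared.

Evidence per SNP enters through the approximate Bayes factor. Given an
effect estimate $\hat\beta$ with sampling variance $V$ and a
$\mathrm{Normal}(0, W)$ prior on the true effect, with shrinkage
$r = W/(W+V)$ and $z = \hat\beta/\sqrt{V}$,

$$\log \mathrm{ABF} = \tfrac12\log(1-r) + \tfrac{r z^2}{2},$$

the exact log ratio of the marginal likelihood of $\hat\beta$ under
$\mathrm{Normal}(0, V+W)$ to that under $\mathrm{Normal}(0, V)$ (the tests
verify this against numerical integration to $10^{-8}$). When only a
p-value, MAF and sample size are available — the situation for the disease
summary statistics — $|z|$ is recovered from the p-value and $V$ is
approximated by $1/\big(2n\,\mathrm{maf}(1-\mathrm{maf})\big)$, divided by
$s(1-s)$ for a case-control trait with case fraction $s$.

Posterior hypothesis weights combine the per-SNP Bayes factors $BF_{ti}$
with $S_t = \sum_i BF_{ti}$ and $S_{12} = \sum_i BF_{1i}BF_{2i}$:

$$h_0 = 1,\quad h_1 = p_1 S_1,\quad h_2 = p_2 S_2,\quad
h_3 = p_1p_2\,(S_1S_2 - S_{12}),\quad h_4 = p_{12} S_{12},$$

normalised to the posterior probabilities $PP_0,\dots,PP_4$. These weights
take the null configuration as the reference (the $p_0$ powers of the prior
algebra cancel to first order); consequently $PP_4/PP_3 \propto p_{12}$
*exactly* at fixed data, which the calibration procedure exploits, and
posterior-to-prior ratio identities hold only to $O(p_1+p_2+p_{12}) \approx
4\times10^{-4}$ — visible in the "uninformative data" test tolerance. All
evidence sums are computed by log-sum-exp: a convincing eQTL can carry
$\log BF$ in the hundreds, and $S_1S_2$ overflows doubles on the natural
scale.

## Parameters that matter

* `p1`, `p2` (default $10^{-4}$): per-SNP causality prior per trait. At
  $10^{-4}$ this is a conservative ~20 expected causal SNPs on a 200K
  array.
* `p12` (default $10^{-6}$): per-SNP shared-causality prior. The default
  implies that one in $(p_1+p_{12})/p_{12} = 101$ SNPs causal for a trait
  is causal for both. This is the single most influential parameter —
  $PP_4/PP_3$ scales linearly in it — and is the target of the empirical
  calibration below.
* `W_cc` ($0.15^2$, log-odds scale) and `W_quant` ($0.2^2$, unit-variance
  trait scale): prior effect-size variances for the Bayes factors, the
  conventional values for these trait types. Expression is standardized per
  probe before fitting so that `W_quant` is on the right scale; this is
  also why `fit_cis_eqtl(standardize = TRUE)` is the pipeline default.
* Classification thresholds: an analysis "overlaps" when
  $PP_3 + PP_4 \ge 0.99$; within overlaps, colocalisation is "suggestive"
  when $PP_4/PP_3 > 1$ and "convincing" when $PP_4/PP_3 > 5$. Reporting is
  additionally gated on association strength: minimum disease p-value
  $\le 5\times10^{-8}$ and minimum eQTL p-value $\le 10^{-10}$. The
  genome-wide significance gate is stated but not numerically fixed in the
  source analyses; $5\times10^{-8}$ is the field's convention and is
  configurable.

## Empirical calibration of p12

There is far less external evidence about $p_{12}$ than about $p_1$ or
$p_2$. The calibration re-runs the posterior computation over a grid of
$p_{12}$ values (default $10^{-7}, 10^{-6}, 10^{-5}$; the per-SNP Bayes
factors are prior-free and reused), restricts at each grid value to
pairwise analyses with $PP_3 + PP_4 > 0.8$, and compares the mean posterior
colocalisation fraction $PP_4/(PP_3+PP_4)$ with the mean prior fraction
$P_4/(P_3+P_4)$ over the included pairs. The chosen $p_{12}$ minimises the
absolute gap; the original procedure was graphical, so the minimum-gap rule
is this package's formalisation. Each pairwise analysis is weighted
equally (region-level weighting is an alternative reading; per-pair matches
what the published figure plots), and the inclusion mask is recomputed per
grid value since $PP_3 + PP_4$ itself grows with $p_{12}$.

## QC rules

Genotyped SNPs are kept when MAF $\ge 0.005$, call rate $\ge 0.99$ and
$|z_{HWE}| \le 4$; imputed SNPs when MAF $\ge 0.005$, $|z_{HWE}| \le 4$ and
info $\ge 0.3$. The printed inequalities are taken literally (boundaries
inclusive on the keep side). $z_{HWE}$ is the signed square root of the
1-df chi-square against Hardy-Weinberg expectations (sign = heterozygote
excess), so $|z| \le 4$ is $\chi^2 \le 16$; the source never defines its z,
and this is the conventional reading. HWE filtering applies to the full
eQTL cohort (case-only subsets are not distinguishable from summary
inputs). Probes must intersect the region extended by ±200 kb (closed
intervals, measured from region boundaries — the most permissive reading);
regions need at least one quality-passing probe and at least 20 "common"
SNPs, interpreted as QC-passing SNPs present in both the disease and eQTL
datasets. Colocalising signals whose peak SNP has $r^2 > 0.6$ with any SNP
overlapping the probe sequence are excluded as potential hybridisation
artefacts.

## The synthetic-data generator

The generator emulates the three real inputs — dense regional haplotypes, a
case-control GWAS summarised to p/MAF, and two independent eQTL cohorts
with dosages and expression — without any access to controlled data.

* **Haplotypes.** A first-order Markov copy process: SNP $k+1$ copies SNP
  $k$'s allele with probability $\rho$, else redraws at its own target
  frequency (uniform on (0.05, 0.5] by default). One parameter gives
  tunable LD decay with known limits ($\rho = 0$: independence). This is
  *not* a coalescent: no recombination hotspots, no allele-frequency /
  LD correlation, no population structure. Green recovery tests therefore
  establish correctness of the inference machinery under generic LD, not
  robustness to real human haplotype structure.
* **Disease cohort.** Individuals pair two random panel haplotypes; disease
  is logistic with a 10% baseline prevalence (chosen once as a realistic
  common-disease figure; the published analyses never condition on
  prevalence) and per-allele log OR at the causal SNP. Cases/controls are
  rejection-sampled to the requested counts; summaries are 1-df allelic
  score-test p-values with control MAF — matching the granularity of the
  real p/MAF input path.
* **eQTL cohorts.** Expression is `beta_expr` × causal dosage (+ half-size
  secondary effect in the `H4_plus_secondary` scenario, planted at the SNP
  with $r^2$ closest to 0.3 with the primary, emulating the published
  primary/secondary eQTL example) + standard normal noise. Studies 1 and 2
  use disjoint fixed sub-seed offsets, so the two cohorts are independent
  draws — the real monocyte studies are combined by fixed-effects
  meta-analysis exactly as here. The B-cell-style "two-thirds overlapping
  individuals" situation is handled by *never* meta-analysing across cell
  types, only across the two monocyte-style studies.
* All generators are pure functions of (arguments, seed); the caller's RNG
  stream is left untouched.

## Numerical and design choices

* Evidence sums in log space throughout (`logsumexp`, and a stable
  `log(exp(a) - exp(b))` for the $S_1S_2 - S_{12}$ term, exactly zero at
  $Q = 1$ so $PP_3 = 0$ there by construction).
* $PP_3 = 0$ with $PP_4 > 0$ yields an infinite posterior ratio, classified
  as convincing.
* OLS per SNP in closed form (pairwise-complete over missing dosages,
  $n-2$ residual denominator, verified against `lm()`); SNPs with constant
  dosage or fewer than 3 complete pairs are skipped with a warning rather
  than fitted.
* Meta-analysis harmonises alleles by exact match or swap (sign flip);
  strand-ambiguous A/T and C/G SNPs with MAF > 0.4 in either study are
  dropped as unresolvable. Probes present in a single study pass through
  un-combined.
* Peak-SNP tie-break: smallest p, then smallest position.
* Response eQTLs are simple per-sample differences (stimulated − baseline),
  standardized; no between-condition normalisation is attempted, a known
  limitation of difference traits on array expression data.
* Missing dosages propagate as missing and are dropped pairwise; duplicate
  SNP ids are an error (ids are the cross-dataset join key), duplicate
  positions are not.
* Enrichment odds ratios are reported both from raw 2×2 counts and as the
  ratio of odds rounded to 3 decimals (`odds_ratio_printed`), because
  published tables print rounded odds and their ratio; the two differ in
  the third decimal.

## Limitations

* Single causal variant per trait per region: where a disease signal
  matches only a *secondary* eQTL, the method correctly does not declare
  colocalisation of the strongest signals; the `H4_plus_secondary` scenario
  exists to exercise exactly this behaviour.
* The p/MAF variance approximation ignores imputation uncertainty and
  covariate adjustment.
* The calibration chooses among grid values only; it is a heuristic
  moment-matching device, not a likelihood-based estimate of $p_{12}$.
* Synthetic LD is Markovian; conclusions about fine-scale resolution on
  real haplotypes are out of scope, and acceptance tests deliberately avoid
  depending on fine LD details.
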