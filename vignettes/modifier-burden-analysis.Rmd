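---
title: "Modifier-variant burden analysis in syndromic CNV cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modifier-variant burden analysis in syndromic CNV cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dup7burden)
```

## The model

The package asks whether rare and low-frequency variants in the genetic
background modify the neuropsychiatric phenotype of individuals who share
a primary pathogenic CNV (the canonical case is the 7q11.23 duplication,
"Dup7"). The unit of inference is a *burden variable*: the per-sample
count of variants that qualify under a class definition (LoF SNVs,
likely-damaging missense SNVs, or rare non-primary CNVs), a frequency
tier, and optionally a gene set. Each burden is regressed on the outcome
with sex and age as covariates:

* binary group membership: maximum-likelihood logistic regression,
  `logit(P(affected)) = b0 + b1·sex + b2·age + B·burden`;
* continuous standard scores (intellectual ability GCA, adaptive
  behaviour BroadInd, symptom severity CSS): ordinary least squares with
  the same design.

The burden coefficient's two-sided Wald p-value is converted to a
directional one-tailed p: deleterious burden is expected to *increase*
the affected-group odds and the severity score and to *decrease* the two
ability scores, so when the fitted sign matches that direction the
one-tailed p is half the two-sided p, and `1 − p/2` otherwise (0.5 at an
exactly zero coefficient). Benjamini–Hochberg q-values are computed over
the converged models of each family — genome-wide models form one family
per outcome; pathway models form one family per (outcome × burden
specification) within each pathway category, a choice consistent with
identical q-values appearing for equal p-values inside one such block. A
model is a hit when the sign is right, the one-tailed p ≤ 0.05 and FDR
≤ 0.15 (both bounds inclusive).

Assumptions worth stating: samples are unrelated and ancestry-homogeneous
(ancestry/kinship screening happens upstream and is out of scope);
covariates enter linearly and unstandardized; the Wald p underlies the
one-tailed conversion (the likelihood-ratio alternative would differ
slightly in small samples); and one burden is tested per model — no
joint multi-burden modelling.

## Variant qualification rules

* **Genotype QC** (`passes_genotype_qc`): caller filters passed AND
  (autosomal het: GQ ≥ 99 and 0.3 ≤ AAF ≤ 0.7) OR (hom or chrX: GQ ≥ 25
  and AAF > 0.7). Boundaries are deliberately asymmetric: the het bounds
  are inclusive, the hom/chrX allele-fraction bound strict, exactly as
  stated by the upstream QC convention the package reproduces.
* **Frequency tiers** (`frequency_tier`): the qualifying frequency is the
  *maximum* across the three database columns — a variant must be rare in
  all of them — with ≤ 1% inclusive for rare and < 5% exclusive for low
  frequency. A variant absent from all three databases is *novel* and
  qualifies at both levels; absence is represented as `NA`, never as 0,
  so it cannot be confused with an observed zero frequency. The 5% tier
  is cumulative (it contains the rare tier); the alternative (1%, 5%)
  band reading is not implemented because tier nesting is what makes the
  two reported levels comparable.
* **Likely-damaging missense** (`is_likely_damaging_missense`): at least
  `k` of 8 predictor votes, canonical `k = 4`. Absent predictions never
  count as damaging and the denominator stays 8 regardless of how many
  are absent — the conservative reading when the prediction source is
  silent. The full `k = 1..8` ladder is exposed because burden analyses
  commonly sweep it (`mis_1` … `mis_8`).
* **Splice filter** (`passes_splice_filter`): any of the four delta
  scores (acceptor/donor gain/loss) ≥ 0.8 and region ≠ intergenic; all
  four absent fails the filter rather than erroring. With
  `include_splice = TRUE` these variants are folded into the LoF class
  for the splice-inclusive rerun.
* **CNVs**: coordinates are 1-based inclusive, so `size = end − start +
  1`; a BED importer shifts half-open starts by +1. The primary locus is
  excluded by 50% reciprocal overlap with a configurable region
  (default chr7:72,700,000–74,200,000, GRCh37); the source convention
  names the exclusion but not an overlap rule, so the reciprocal-overlap
  default is this package's choice and a parameter. CNV rarity is taken
  from input annotation — database comparison is upstream. Within a gene
  set a CNV counts once per sample, not once per overlapped gene,
  avoiding length-driven inflation.

## Tunable parameters

| parameter | default | units | where |
|---|---|---|---|
| het GQ / AAF bounds | 99, [0.3, 0.7] | phred / fraction | `passes_genotype_qc` |
| hom/chrX GQ / AAF | 25, > 0.7 | phred / fraction | `passes_genotype_qc` |
| rare / low-frequency levels | 0.01 (≤), 0.05 (<) | allele frequency | `frequency_tier` |
| damaging-vote threshold `mis_k` | 4 | votes of 8 | `burden_spec` |
| splice delta threshold | 0.8 | delta score | `passes_splice_filter` |
| primary region + reciprocal overlap | Dup7 locus, 0.5 | coords / fraction | `is_primary_locus` |
| GO/KEGG set-size bounds | [100, 1000] | genes | `filter_gene_sets` |
| gate thresholds | p ≤ 0.05, FDR ≤ 0.15 | probabilities | `significance_gate` |

The GO/KEGG size bound is applied to the raw set size by default;
`filter_gene_sets(covered_genes = …)` applies it after intersecting with
the genes covered by the data instead. Both application points are
defensible — published hit tables can show small GO sets when coverage
intersection happens elsewhere in the chain — so the point of application
is a parameter rather than a fixed rule.

## What the synthetic cohort emulates

`simulation_config()` defaults encode the study conditions the package is
modelled on: 20 carriers, an average of 185 rare coding SNVs/indels and
35.4 rare coding CNVs per genome, one primary duplication per sample
(mean 1.6 Mb with 120 kb jitter), a ~45% affected fraction, ages 4–17,
and splice-disrupting noncoding variants at the cohort rates reported
there (29 rare + 46 low-frequency over 20 genomes → per-sample means 1.45
and 0.85). Strata that the source cohort does not quantify are fixed
design choices: a low-frequency-only coding stratum (mean 60/sample), a
small common stratum (mean 30/sample — enough to exercise the frequency
filters, which is its only role, since common variants are excluded from
every analysis), sub-threshold noncoding variants (mean 10/sample), and a
5% QC-failure rate so the QC filters have work to do. Coding class
proportions are 5% LoF, 50% missense, 35% synonymous, 10% non-frameshift
indel; LoF splits 50/35/15 into nonsense / frameshift / core splice-site.
Clinical scores are drawn per group with SD 10 for the two standard
scores — tighter than the population SD of 15, as expected for a
diagnostically homogeneous clinical cohort, and chosen up front so that
the package's reference recovery experiments (slope −2 on GCA at n = 100)
operate at reasonable power. Frequencies are drawn per stratum with one
database carrying the stratum's qualifying frequency and the others
jittered below it or missing (10% per database), which pins the
max-across-databases rule exactly to the stratum boundaries; novel
variants (35% of rare) have all three absent.

Injected effects are additive on the outcome scale for continuous scores
and on the log-odds scale (centred, so group balance is preserved) for
the binary outcome — matching the fitted model families so that
"recovery" is well defined. The injected burden is computed on the
QC-passing variants with exactly the spec the pipeline will use, and the
truth manifest records the injected slopes and realized mean burdens.

What the generator does *not* emulate: linkage disequilibrium and
haplotype structure, trio inheritance, mutation-rate heterogeneity along
the genome, gene length variation (all synthetic genes are 50 kb on a
100 kb grid), correlated predictor errors, and ancestry stratification.
Passing tests therefore demonstrate that the pipeline's *statistical
machinery* behaves as claimed under its own assumptions — calibrated
type-I error, unbiased recovery, correct bookkeeping — not that those
properties survive the confounding structure of real cohorts.

## Numerical choices

* Logistic non-convergence and (quasi-)separation — plausible at n = 20 —
  are detected (fitted probabilities numerically 0/1, or IRLS
  non-convergence) and reported as `converged = FALSE`; such models are
  excluded from their FDR family rather than silently repaired. A weak
  ridge-penalized fallback exists behind `penalized = TRUE`, off by
  default.
* Zero-variance burdens and models with fewer than 6 samples return
  non-converged results instead of fitting degenerate designs; samples
  missing an outcome are dropped per model with a message, not
  cohort-wide.
* `bh_fdr()` delegates to `stats::p.adjust(method = "BH")`; the test
  suite checks it against a brute-force evaluation of the step-up
  definition.
* The Mann–Whitney test is implemented in-package because the analysis
  reports U and z alongside p: exact enumeration of all group assignments
  for pooled n ≤ 12 (two-sided p = probability of a U at least as far
  from its mean as observed), and otherwise the normal approximation with
  tie correction and *no* continuity correction — the convention that
  matches a reported z of 0.80 with a two-sided p of 0.424. The normal
  branch is cross-checked against `wilcox.test(correct = FALSE)`.
* The Fisher exact test uses `stats::fisher.test`, whose two-sided
  probability-mass convention (summing tables no more probable than the
  observed one) is the one reproducing the reference parent-of-origin
  p-value of 0.656; the tests compare it to direct hypergeometric
  enumeration.
* Group SDs are reported as sample (n−1) standard deviations.

## Problem sizes in the validation suite

The simulation-based checks run at sizes chosen to give stable Monte
Carlo estimates while remaining desk-scale: type-I error on 500 null
cohorts of n = 100; effect recovery over 200 seeds per injected effect
(slope −2 on GCA through a 1500-gene set; log-odds +1.5 on group through
a 200-gene set — the binary effect uses a smaller set so the log-odds
spread stays in the range where the MLE is well behaved); oracle
comparisons over 1,000 random p-vectors and 10,000 random 2×2 tables.
Invariant checks (tier nesting, `mis_k` monotonicity, QC idempotence, the
all-gene reduction identity) run on seeded cohorts of 20 samples.

## Known limitations

Small-cohort logistic burden models are fragile: with n = 20 and sparse
burdens, separation is common and the package deliberately reports it
rather than producing a number. The FDR family definition is a
convention, configurable via `adjust_fdr_families()`; different
family choices change q-values, not coefficients. The gene-set
collections bundled with the simulator are schema placeholders — real
analyses should supply curated GMTs. And the reduction identity
(all-gene set ≡ genome-wide burden) holds exactly for SNV classes but
for CNVs only when every counted CNV overlaps at least one annotated
gene, which the generator guarantees by construction and real data need
not.
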