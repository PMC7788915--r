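Package: dup7burden
Title: Rare-Variant Modifier Burden Analysis for Syndromic CNV Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Covariate-adjusted rare and low-frequency variant burden
    analysis for small syndromic copy-number-variant cohorts, modelled on
    whole-genome modifier studies of the 7q11.23 duplication (Dup7)
    phenotype. Provides genotype-quality and allele-balance filtering,
    population-frequency tiering, loss-of-function and damaging-missense
    classification with in-silico prediction vote counting, cryptic-splice
    variant filtering from SpliceAI-style delta scores, per-sample burden
    construction genome-wide and within gene sets, sign-constrained
    one-tailed logistic and linear regression against neuropsychiatric
    outcomes with Benjamini-Hochberg false-discovery-rate control,
    cohort-level descriptive statistics, and a synthetic genotype-phenotype
    cohort generator with injectable burden-phenotype effects for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
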