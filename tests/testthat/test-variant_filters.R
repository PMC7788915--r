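test_that("genotype QC applies the het/hom/chrX boundary rules", {
  cases <- variant_table(
    variant_row("S1", gq = 99, aaf = 0.30),                      # pass
    variant_row("S1", gq = 98, aaf = 0.50),                      # fail: GQ
    variant_row("S1", gq = 99, aaf = 0.70),                      # pass: upper
    variant_row("S1", gq = 99, aaf = 0.71),                      # fail: AAF
    variant_row("S1", chrom = "chrX", gq = 25, aaf = 0.71),      # pass
    variant_row("S1", chrom = "chrX", gq = 25, aaf = 0.70),      # fail: strict >
    variant_row("S1", zygosity = "hom", gq = 25, aaf = 0.95),    # pass
    variant_row("S1", zygosity = "hom", gq = 24, aaf = 0.95),    # fail: GQ
    variant_row("S1", gq = 99, aaf = 0.5, passed = FALSE))       # fail: caller
  expect_equal(passes_genotype_qc(cases),
               c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
})

test_that("unrecognized chromosomes are rejected with a warning", {
  v <- variant_row("S1", chrom = "weird_contig")
  expect_warning(ok <- passes_genotype_qc(v), "unrecognized")
  expect_false(ok)
})

test_that("QC filtering is idempotent", {
  set.seed(42)
  co <- generate_cohort(simulation_config(n_samples = 10, seed = 42))
  once <- co$variants[passes_genotype_qc(co$variants), ]
  expect_true(all(passes_genotype_qc(once)))
  twice <- once[passes_genotype_qc(once), ]
  expect_equal(once, twice)
})

test_that("splice filter needs a present delta >= 0.8 outside intergenic", {
  cases <- variant_table(
    variant_row("S1", region = "intronic", effect = "noncoding_other",
                spliceai = c(0.81, 0.1, 0, 0)),
    variant_row("S1", region = "intronic", effect = "noncoding_other",
                spliceai = c(0.79, 0.79, 0.79, 0.79)),
    variant_row("S1", region = "intergenic", effect = "noncoding_other",
                spliceai = c(0.95, 0, 0, 0)),
    variant_row("S1", region = "intronic", effect = "noncoding_other",
                spliceai = c(NA, NA, NA, NA)),
    variant_row("S1", region = "intronic", effect = "noncoding_other",
                spliceai = c(NA, 0.8, NA, NA)))
  expect_equal(passes_splice_filter(cases),
               c(TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("frequency tiers use the max-across-databases rule", {
  v1 <- variant_row("S1", freqs = c(0.005, 0.009, NA))
  v2 <- variant_row("S1", freqs = c(0.005, 0.02, 0.001))
  v3 <- variant_row("S1", freqs = c(NA, NA, NA))
  v4 <- variant_row("S1", freqs = c(0.01, NA, NA))   # inclusive at 1%
  v5 <- variant_row("S1", freqs = c(0.05, NA, NA))   # exclusive at 5%
  expect_true(frequency_tier(v1, 0.01))
  expect_false(frequency_tier(v2, 0.01))
  expect_true(frequency_tier(v2, 0.05))
  expect_true(frequency_tier(v3, 0.01))
  expect_true(frequency_tier(v3, 0.05))
  expect_true(frequency_tier(v4, 0.01))
  expect_false(frequency_tier(v5, 0.05))
})

test_that("tier nesting: rare variants always qualify at the 5% level", {
  co <- generate_cohort(simulation_config(n_samples = 20, seed = 3))
  rare <- frequency_tier(co$variants, 0.01)
  low <- frequency_tier(co$variants, 0.05)
  expect_true(all(low[rare]))
})

test_that("likely-damaging missense counts damaging votes, absent never counts", {
  v4 <- variant_row("S1", preds = c(rep("damaging", 4), rep("benign", 4)))
  v3 <- variant_row("S1", preds = c(rep("damaging", 3), rep(NA, 5)))
  expect_true(is_likely_damaging_missense(v4, k = 4))
  expect_false(is_likely_damaging_missense(v3, k = 4))
  expect_true(is_likely_damaging_missense(v3, k = 3))
  expect_error(is_likely_damaging_missense(
    variant_row("S1", effect = "nonsense")), "non-missense")
})

test_that("mis_k thresholds are monotone on a generated cohort", {
  co <- generate_cohort(simulation_config(n_samples = 20, seed = 5))
  mis <- co$variants[co$variants$effect == "missense", ]
  prev <- is_likely_damaging_missense(mis, 1)
  for (k in 2:8) {
    cur <- is_likely_damaging_missense(mis, k)
    expect_true(all(prev[cur]), info = paste("k =", k))
    prev <- cur
  }
})

test_that("functional classes map effects; splice inclusion folds into lof", {
  v <- variant_table(
    variant_row("S1", effect = "nonsense"),
    variant_row("S1", effect = "synonymous"),
    variant_row("S1", effect = "noncoding_other", region = "intronic",
                spliceai = c(0.9, 0, 0, 0)),
    variant_row("S1", effect = "nonframeshift_indel"))
  expect_equal(functional_class(v, include_splice = FALSE),
               c("lof", "synonymous", "splice_disrupting_noncoding",
                 "nonframeshift_indel"))
  expect_equal(functional_class(v, include_splice = TRUE),
               c("lof", "synonymous", "lof", "nonframeshift_indel"))
})

test_that("cnv_size matches the 1-based inclusive convention", {
  cnvs <- rbind(cnv_row(start = 146303401L, end = 147891400L),
                cnv_row(start = 110347001L, end = 110883800L),
                cnv_row(start = 111120394L, end = 111351748L),
                cnv_row(start = 100L, end = 100L))
  expect_equal(cnv_size(cnvs), c(1588000L, 536800L, 231355L, 1L))
})

test_that("cnv_size agrees with base enumeration on small spans", {
  set.seed(9)
  for (i in 1:25) {
    s <- sample.int(1e6, 1)
    e <- s + sample.int(1e4, 1) - 1L
    expect_equal(cnv_size(cnv_row(start = s, end = e)),
                 length(seq.int(s, e)))
  }
})

test_that("gene overlap is inclusive at single-base resolution", {
  gm <- data.frame(gene = c("GX", "GY"), chrom = "chr1",
                   start = c(1000L, 5000L), end = c(1999L, 5999L))
  cnvs <- rbind(cnv_row(start = 900L, end = 2100L),    # spans GX
                cnv_row(start = 100L, end = 999L),     # ends 1 bp before GX
                cnv_row(start = 1999L, end = 2500L),   # 1 bp overlap
                cnv_row(start = 3000L, end = 4999L))   # abuts GY hitting it? no: 4999 < 5000
  ann <- annotate_cnv_genes(cnvs, gm)
  expect_equal(ann$genes, c("GX", "", "GX", ""))
})

test_that("primary-locus exclusion uses reciprocal overlap", {
  cnvs <- rbind(
    cnv_row(chrom = "chr7", start = 72700000L, end = 74200000L,
            cnv_type = "DUP"),                       # exact region
    cnv_row(chrom = "chr7", start = 72600000L, end = 74300000L,
            cnv_type = "DUP"),                       # slightly larger
    cnv_row(chrom = "chr7", start = 110347001L, end = 110883800L),
    cnv_row(chrom = "chr1", start = 72700000L, end = 74200000L))
  expect_equal(is_primary_locus(cnvs), c(TRUE, TRUE, FALSE, FALSE))
})
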