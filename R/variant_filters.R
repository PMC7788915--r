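## variant_filters: genotype-quality QC, frequency tiers, functional
## classification, splice filtering, and rare-CNV preparation.

.DEFAULT_AUTOSOMES <- c(as.character(1:22), paste0("chr", 1:22))

.is_chrx <- function(chrom) chrom %in% c("X", "chrX")

#' Genotype-quality and allele-balance filter
#'
#' A call passes when the upstream caller filters passed and either
#' (autosomal heterozygous) GQ >= 99 with allele fraction in \[0.3, 0.7\],
#' or (homozygous, or any call on chromosome X) GQ >= 25 with allele
#' fraction > 0.7. Calls on chromosomes outside the autosome list that are
#' not chrX are rejected with a warning.
#'
#' @param variants a variant data frame.
#' @param autosomes chromosome names treated as autosomal.
#' @return logical vector, one element per variant row.
#' @export
passes_genotype_qc <- function(variants, autosomes = .DEFAULT_AUTOSOMES) {
  chrom <- variants$chrom
  autosomal <- chrom %in% autosomes
  chrx <- .is_chrx(chrom)
  unknown <- !autosomal & !chrx
  if (any(unknown))
    warning("passes_genotype_qc: rejecting ", sum(unknown),
            " call(s) on unrecognized chromosome(s): ",
            paste(unique(chrom[unknown]), collapse = ", "))
  het_rule <- autosomal & variants$zygosity == "het" &
    variants$gq >= 99 & variants$aaf >= 0.3 & variants$aaf <= 0.7
  hom_rule <- (variants$zygosity == "hom" | chrx) &
    variants$gq >= 25 & variants$aaf > 0.7
  ok <- variants$passed_caller_filters & (het_rule | hom_rule) & !unknown
  ok & !is.na(ok)
}

#' Cryptic-splice variant filter
#'
#' Passes when the maximum of the present SpliceAI-style delta scores
#' (acceptor/donor gain/loss) meets the threshold and the variant is not
#' intergenic. Variants with all four deltas absent fail.
#'
#' @param variants a variant data frame.
#' @param threshold minimum delta score (default 0.8).
#' @return logical vector.
#' @export
passes_splice_filter <- function(variants, threshold = 0.8) {
  dmax <- do.call(pmax, c(unname(variants[, .SPLICE_COLS, drop = FALSE]),
                          na.rm = TRUE))
  !is.na(dmax) & dmax >= threshold & variants$region != "intergenic"
}

#' Qualifying population frequency
#'
#' The maximum frequency across the three reference databases; variants
#' absent from all three are "novel" and return `NA`.
#'
#' @param variants a variant data frame.
#' @return numeric vector (`NA` = novel).
#' @export
qualifying_frequency <- function(variants) {
  do.call(pmax, c(unname(variants[, .FREQ_COLS, drop = FALSE]),
                  na.rm = TRUE))
}

#' Frequency-tier qualification
#'
#' A variant qualifies at the rare level when its qualifying frequency
#' (maximum across databases) is <= 1%, and at the low-frequency level when
#' it is < 5%; novel variants (absent from all databases) qualify at both.
#' The 5% tier is cumulative, so every rare variant also qualifies at 5%.
#'
#' @param variants a variant data frame.
#' @param level `0.01` (rare, inclusive bound) or `0.05` (low frequency,
#'   exclusive bound).
#' @return logical vector.
#' @export
frequency_tier <- function(variants, level = c(0.01, 0.05)) {
  level <- match.arg(as.character(level[1]), c("0.01", "0.05"))
  f <- qualifying_frequency(variants)
  novel <- is.na(f)
  if (level == "0.01") novel | (f <= 0.01 & !novel)
  else novel | (f < 0.05 & !novel)
}

#' Count damaging in-silico prediction votes
#'
#' Counts, per variant, how many of the eight predictors (CADD, SIFT,
#' PolyPhen, Provean, MutationAssessor, MutationTaster, PhyloPMam,
#' PhyloPVert) call the variant damaging. Absent predictions never count
#' as damaging votes.
#'
#' @param variants a variant data frame.
#' @return integer vector in 0..8.
#' @export
damaging_vote_count <- function(variants) {
  p <- as.matrix(variants[, .PRED_COLS, drop = FALSE])
  as.integer(rowSums(p == "damaging", na.rm = TRUE))
}

#' Likely-damaging missense classification
#'
#' A missense variant is likely damaging when at least `k` of the eight
#' in-silico predictors call it damaging; the canonical definition uses
#' `k = 4`. Calling this on non-missense rows is a contract violation.
#'
#' @param variants a variant data frame; every row must have
#'   `effect == "missense"`.
#' @param k minimum number of damaging votes, 1..8 (default 4).
#' @return logical vector.
#' @export
is_likely_damaging_missense <- function(variants, k = 4) {
  stopifnot(k >= 1, k <= 8)
  if (any(variants$effect != "missense"))
    stop("is_likely_damaging_missense: non-missense variant(s) supplied")
  damaging_vote_count(variants) >= k
}

#' Functional classification of variants
#'
#' Maps the annotated effect to a functional class: `lof` for frameshift
#' indels, nonsense, and core splice-site variants; `missense`,
#' `synonymous` and `nonframeshift_indel` pass through; everything else is
#' `splice_disrupting_noncoding` when it passes the splice filter, else
#' `other`. With `include_splice = TRUE`, splice-filter-passing variants
#' not already LoF are absorbed into `lof` (the splice-inclusive rerun).
#'
#' @param variants a variant data frame.
#' @param include_splice fold splice-disrupting variants into `lof`?
#' @param splice_threshold delta-score threshold for the splice filter.
#' @return character vector of classes.
#' @export
functional_class <- function(variants, include_splice = FALSE,
                             splice_threshold = 0.8) {
  cls <- rep("other", nrow(variants))
  cls[variants$effect %in% .LOF_EFFECTS] <- "lof"
  cls[variants$effect == "missense"] <- "missense"
  cls[variants$effect == "synonymous"] <- "synonymous"
  cls[variants$effect == "nonframeshift_indel"] <- "nonframeshift_indel"
  splice <- passes_splice_filter(variants, splice_threshold) & cls != "lof"
  if (include_splice) cls[splice] <- "lof"
  else cls[splice & cls %in% c("other")] <- "splice_disrupting_noncoding"
  cls
}

#' CNV size in base pairs
#'
#' Coordinates are 1-based inclusive, so size = end - start + 1.
#'
#' @param cnvs a CNV data frame (or any data frame with `start`/`end`).
#' @return integer vector of sizes.
#' @export
cnv_size <- function(cnvs) {
  as.integer(cnvs$end - cnvs$start + 1L)
}

#' Annotate CNVs with overlapped genes
#'
#' Fills the `genes` column with the symbols of gene models overlapping the
#' CNV by at least one base (1-based inclusive intervals on both sides).
#'
#' @param cnvs a CNV data frame.
#' @param gene_models data frame with `gene, chrom, start, end` (1-based
#'   inclusive).
#' @return the CNV data frame with `genes` filled (comma-separated).
#' @export
annotate_cnv_genes <- function(cnvs, gene_models) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gene_models)))
  cnvs$genes <- vapply(seq_len(nrow(cnvs)), function(i) {
    g <- gene_models[gene_models$chrom == cnvs$chrom[i] &
                       gene_models$start <= cnvs$end[i] &
                       gene_models$end >= cnvs$start[i], "gene"]
    paste(g, collapse = ",")
  }, "")
  cnvs
}

#' Primary-locus (Dup7) CNV exclusion
#'
#' Flags CNVs that reciprocally overlap the configured primary region
#' above a fraction of both lengths; such calls are the shared primary
#' pathogenic CNV and are excluded from modifier burden counting.
#'
#' @param cnvs a CNV data frame.
#' @param primary_region `list(chrom, start, end)`; default is the Dup7
#'   locus chr7:72,700,000-74,200,000 (GRCh37).
#' @param min_reciprocal minimum reciprocal overlap fraction (default 0.5).
#' @return logical vector: `TRUE` where the CNV is the primary locus.
#' @export
is_primary_locus <- function(cnvs, primary_region = .DUP7_REGION,
                             min_reciprocal = 0.5) {
  ov_start <- pmax(cnvs$start, primary_region$start)
  ov_end <- pmin(cnvs$end, primary_region$end)
  ov <- pmax(0, ov_end - ov_start + 1)
  size_c <- cnv_size(cnvs)
  size_p <- primary_region$end - primary_region$start + 1
  cnvs$chrom == primary_region$chrom &
    ov / size_c >= min_reciprocal & ov / size_p >= min_reciprocal
}
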