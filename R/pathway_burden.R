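## pathway_burden: gene-set-restricted burdens and the function/pathway
## enrichment regression scan, with the splice-inclusive rerun.

#' Filter gene sets by size
#'
#' GO and KEGG sets outside the size bounds (inclusive; default 100-1000
#' genes) are removed; curated ASD-risk and neuro-related collections are
#' kept regardless of size. The bound is applied to the raw set size by
#' default; pass `covered_genes` to apply it after intersecting each set
#' with the genes actually covered by the variant data instead.
#'
#' @param sets list of gene sets (see [read_gene_sets()]).
#' @param size_bounds length-2 inclusive bounds for GO/KEGG sets.
#' @param bounded_categories categories the bounds apply to.
#' @param covered_genes optional character vector; when supplied, sizes are
#'   measured on the intersection with it.
#' @return the filtered list.
#' @export
filter_gene_sets <- function(sets, size_bounds = c(100, 1000),
                             bounded_categories = c("GO", "KEGG"),
                             covered_genes = NULL) {
  keep <- vapply(sets, function(s) {
    if (!s$category %in% bounded_categories) return(TRUE)
    n <- if (is.null(covered_genes)) length(s$genes) else
      length(intersect(s$genes, covered_genes))
    n >= size_bounds[1] && n <= size_bounds[2]
  }, TRUE)
  sets[keep]
}

#' Gene-set-restricted burden
#'
#' Identical counting to [compute_burden()], restricted to variants whose
#' gene is a member of the set (CNVs count once per sample when any
#' overlapped gene is a member).
#'
#' @inheritParams compute_burden
#' @param gene_set a gene set `list(name, category, genes)`.
#' @return a burden matrix; see [compute_burden()].
#' @export
gene_set_burden <- function(variants, cnvs, phenotypes, spec, gene_set, ...) {
  compute_burden(variants, cnvs, phenotypes, spec, gene_set = gene_set, ...)
}

#' Pathway-scan configuration
#'
#' @param burden_specs list of [burden_spec()]s to scan.
#' @param outcomes outcomes to model.
#' @param size_bounds GO/KEGG size bounds for [filter_gene_sets()].
#' @param p_max,fdr_max significance-gate thresholds.
#' @param splice_threshold SpliceAI delta threshold.
#' @param primary_region primary-locus region for CNV exclusion.
#' @return a `pathway_scan_config` list.
#' @export
pathway_scan_config <- function(burden_specs = default_pathway_specs(),
                                outcomes = .OUTCOMES,
                                size_bounds = c(100, 1000),
                                p_max = 0.05, fdr_max = 0.15,
                                splice_threshold = 0.8,
                                primary_region = .DUP7_REGION) {
  structure(list(burden_specs = burden_specs, outcomes = outcomes,
                 size_bounds = size_bounds, p_max = p_max,
                 fdr_max = fdr_max, splice_threshold = splice_threshold,
                 primary_region = primary_region),
            class = "pathway_scan_config")
}

#' Default pathway-scan burden specifications
#'
#' LoF, likely-damaging missense (4 of 8 votes), and non-primary CNV
#' burdens, each at the rare (1%) and low-frequency (5%) levels.
#'
#' @return list of [burden_spec()]s.
#' @export
default_pathway_specs <- function() {
  list(burden_spec("lof_snv", 0.01), burden_spec("lof_snv", 0.05),
       burden_spec("missense_snv", 0.01, mis_k = 4),
       burden_spec("missense_snv", 0.05, mis_k = 4),
       burden_spec("cnv_non_primary", 0.01),
       burden_spec("cnv_non_primary", 0.05))
}

#' Function/pathway enrichment regression scan
#'
#' For every combination of outcome, burden specification, and size-
#' filtered gene set, builds the set-restricted burden and fits the
#' covariate-adjusted model. Benjamini-Hochberg FDR is computed within
#' families defined by (outcome x burden spec) inside each pathway
#' category, over converged models only. The full per-set table doubles as
#' the volcano table (plot coefficient B against signed -log10 one-tailed
#' p); [significance_gate()] selects the hits table.
#'
#' @param variants QC-passed variant data frame.
#' @param cnvs CNV data frame.
#' @param phenotypes phenotype data frame.
#' @param gene_sets list of gene sets.
#' @param config a [pathway_scan_config()].
#' @param convention sign convention.
#' @return association-results data frame, one row per model, with a
#'   `gated` column.
#' @export
run_pathway_scan <- function(variants, cnvs, phenotypes, gene_sets,
                             config = pathway_scan_config(),
                             convention = default_sign_convention()) {
  sets <- filter_gene_sets(gene_sets, config$size_bounds)
  rows <- list()
  for (sp in config$burden_specs) {
    for (gs in sets) {
      b <- gene_set_burden(variants, cnvs, phenotypes, sp, gs,
                           splice_threshold = config$splice_threshold,
                           primary_region = config$primary_region)
      for (oc in config$outcomes) {
        r <- fit_outcome_model(b, phenotypes, oc, convention)
        r$category <- gs$category
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else .empty_result()
  res <- adjust_fdr_families(res)
  res$gated <- significance_gate(res, config$p_max, config$fdr_max,
                                 convention)
  res
}

#' Splice-inclusive rerun of the pathway scan
#'
#' Repeats the scan with splice-filter-passing variants folded into the
#' LoF burden variable at both frequency levels (non-LoF specs are left
#' unchanged and not re-fit). Results carry `include_splice = TRUE` and a
#' `rerun` flag.
#'
#' @inheritParams run_pathway_scan
#' @return association-results data frame for the rerun LoF models.
#' @export
splice_inclusive_rerun <- function(variants, cnvs, phenotypes, gene_sets,
                                   config = pathway_scan_config(),
                                   convention = default_sign_convention()) {
  lof_specs <- Filter(function(s) s$variant_class == "lof_snv",
                      config$burden_specs)
  lof_specs <- lapply(lof_specs, function(s) {
    s$include_splice <- TRUE
    s
  })
  cfg <- config
  cfg$burden_specs <- lof_specs
  res <- run_pathway_scan(variants, cnvs, phenotypes, gene_sets, cfg,
                          convention)
  if (nrow(res)) res$rerun <- TRUE
  res
}

#' Count splice-filter-passing variants per frequency level
#'
#' Reports how many QC-passed variants qualify as splice-disrupting at the
#' rare and low-frequency levels (cohort-wide totals, one row per level).
#'
#' @param variants QC-passed variant data frame.
#' @param splice_threshold delta-score threshold.
#' @return data frame `frequency_level, n_splice_variants`.
#' @export
count_splice_variants <- function(variants, splice_threshold = 0.8) {
  sp <- passes_splice_filter(variants, splice_threshold)
  data.frame(
    frequency_level = c(0.01, 0.05),
    n_splice_variants = c(sum(sp & frequency_tier(variants, 0.01)),
                          sum(sp & frequency_tier(variants, 0.05))))
}

#' Volcano table
#'
#' Per-set quantities for a volcano display: coefficient B on the x axis
#' and -log10 one-tailed p on the y axis, for all tested sets (gated or
#' not), so the plotted universe matches the scanned universe.
#'
#' @param results scan results from [run_pathway_scan()].
#' @return data frame `gene_set, category, outcome, variant_class,
#'   frequency_level, B, p, fdr, neg_log10_p, n_genes, n_variants, gated`.
#' @export
volcano_table <- function(results) {
  data.frame(gene_set = results$gene_set, category = results$category,
             outcome = results$outcome,
             variant_class = results$variant_class,
             frequency_level = results$frequency_level,
             B = results$coefficient_B, p = results$p_one_tailed,
             fdr = results$fdr,
             neg_log10_p = -log10(results$p_one_tailed),
             n_genes = results$n_genes,
             n_variants = results$n_variants_observed,
             gated = results$gated,
             stringsAsFactors = FALSE)
}
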