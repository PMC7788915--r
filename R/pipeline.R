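## pipeline: end-to-end wiring of the modules, a YAML-free run
## configuration, and the functions the command-line wrapper dispatches to.

#' Run configuration
#'
#' Bundles input paths, thresholds, and scan settings for an end-to-end
#' run. All thresholds default to the pipeline's canonical values
#' (one-tailed p <= 0.05, FDR <= 0.15, splice delta >= 0.8, GO/KEGG set
#' size 100-1000).
#'
#' @param variants,cnvs,phenotypes,gene_sets input file paths (variant
#'   table, CNV table, phenotype table, GMT).
#' @param out_dir output directory for artifacts.
#' @param p_max,fdr_max,splice_threshold,size_bounds thresholds.
#' @param frequency_levels frequency levels to scan.
#' @param outcomes outcomes to model.
#' @param primary_region primary-locus region.
#' @param seed integer seed (only synthetic-data generation consumes it;
#'   fitting is deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(variants = NULL, cnvs = NULL, phenotypes = NULL,
                       gene_sets = NULL, out_dir = ".",
                       p_max = 0.05, fdr_max = 0.15,
                       splice_threshold = 0.8, size_bounds = c(100, 1000),
                       frequency_levels = c(0.01, 0.05),
                       outcomes = .OUTCOMES,
                       primary_region = .DUP7_REGION, seed = 1) {
  stopifnot(p_max > 0, p_max <= 1, fdr_max > 0, fdr_max <= 1)
  structure(as.list(environment()), class = "run_config")
}

.load_inputs <- function(config) {
  list(variants = read_variants(config$variants),
       cnvs = read_cnvs(config$cnvs),
       phenotypes = read_phenotypes(config$phenotypes),
       gene_sets = if (is.null(config$gene_sets)) list() else
         read_gene_sets(config$gene_sets))
}

#' Run genotype QC and write the filtered variant table
#'
#' @param config a [run_config()].
#' @return path of the filtered table, invisibly.
#' @export
cmd_qc <- function(config) {
  inp <- .load_inputs(config)
  ok <- passes_genotype_qc(inp$variants)
  message("qc: ", sum(ok), " of ", length(ok), " variants pass")
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir,
                                              recursive = TRUE)
  write_variants(inp$variants[ok, , drop = FALSE],
                 file.path(config$out_dir, "variants_qc.tsv"))
}

#' Run the genome-wide burden analysis and control models
#'
#' @param config a [run_config()].
#' @return invisible list of the primary and control results (also written
#'   as TSVs under `out_dir`).
#' @export
cmd_burden <- function(config) {
  inp <- .load_inputs(config)
  v <- inp$variants[passes_genotype_qc(inp$variants), , drop = FALSE]
  res <- run_burden_analysis(v, inp$cnvs, inp$phenotypes,
                             outcomes = config$outcomes,
                             primary_region = config$primary_region)
  ctl <- run_control_models(v, inp$cnvs, inp$phenotypes,
                            outcomes = config$outcomes,
                            primary_region = config$primary_region)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir,
                                              recursive = TRUE)
  write_results(res, file.path(config$out_dir, "burden_results.tsv"))
  write_results(ctl, file.path(config$out_dir, "burden_controls.tsv"))
  invisible(list(primary = res, controls = ctl))
}

#' Run the pathway scan (and the splice-inclusive rerun)
#'
#' @param config a [run_config()].
#' @param include_splice_rerun also run the splice-inclusive LoF rerun?
#' @return invisible list of scan results (also written as TSVs).
#' @export
cmd_pathway <- function(config, include_splice_rerun = TRUE) {
  inp <- .load_inputs(config)
  v <- inp$variants[passes_genotype_qc(inp$variants), , drop = FALSE]
  scfg <- pathway_scan_config(outcomes = config$outcomes,
                              size_bounds = config$size_bounds,
                              p_max = config$p_max,
                              fdr_max = config$fdr_max,
                              splice_threshold = config$splice_threshold,
                              primary_region = config$primary_region)
  scan <- run_pathway_scan(v, inp$cnvs, inp$phenotypes, inp$gene_sets, scfg)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir,
                                              recursive = TRUE)
  write_results(scan, file.path(config$out_dir, "pathway_scan.tsv"))
  write_results(volcano_table(scan),
                file.path(config$out_dir, "volcano.tsv"))
  write_results(scan[scan$gated, , drop = FALSE],
                file.path(config$out_dir, "pathway_hits.tsv"))
  out <- list(scan = scan)
  if (include_splice_rerun) {
    rerun <- splice_inclusive_rerun(v, inp$cnvs, inp$phenotypes,
                                    inp$gene_sets, scfg)
    write_results(rerun, file.path(config$out_dir,
                                   "pathway_scan_splice_rerun.tsv"))
    out$rerun <- rerun
  }
  invisible(out)
}

#' Run the cohort descriptive statistics
#'
#' @param config a [run_config()].
#' @return invisible [run_cohort_stats()] result (also written as TSVs).
#' @export
cmd_stats <- function(config) {
  inp <- .load_inputs(config)
  st <- run_cohort_stats(inp$cnvs, inp$phenotypes, config$primary_region)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir,
                                              recursive = TRUE)
  write_results(st$score_comparisons,
                file.path(config$out_dir, "score_comparisons.tsv"))
  utils::write.table(
    data.frame(measure = "parent_of_origin_fisher_p",
               value = st$origin_fisher_p),
    file.path(config$out_dir, "origin_fisher.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  write_results(st$dup7_sizes$by_group,
                file.path(config$out_dir, "dup7_sizes.tsv"))
  invisible(st)
}

#' Generate and write a synthetic cohort
#'
#' @param config a [run_config()] (its `seed` and `out_dir` are used).
#' @param sim_config optional [simulation_config()]; defaults to the
#'   standard study conditions with the run seed.
#' @return invisible cohort.
#' @export
cmd_simulate <- function(config, sim_config = NULL) {
  if (is.null(sim_config)) sim_config <- simulation_config(seed = config$seed)
  cohort <- generate_cohort(sim_config)
  write_cohort(cohort, config$out_dir)
  invisible(cohort)
}
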