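## synthetic_cohort: generate complete synthetic inputs (variants, CNVs,
## phenotypes, gene sets) with the statistical structure the analysis
## assumes, including injectable burden-phenotype effects.

#' Synthetic-cohort configuration
#'
#' Defaults emulate the motivating study conditions: 20 carriers of a
#' shared primary duplication, an average of 185 rare coding SNVs/indels
#' and 35.4 rare coding CNVs per genome, and splice-disrupting noncoding
#' variants at the cohort rates observed there (29 rare and 46
#' low-frequency over 20 genomes). Strata the source cohort does not
#' quantify (low-frequency-only and common coding variants, sub-threshold
#' noncoding variants) use fixed defaults documented in the methods
#' vignette.
#'
#' @param n_samples cohort size (>= 6).
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @param mean_rare_coding_snvs per-sample mean rare (<= 1%) coding
#'   SNV/indel count.
#' @param mean_lowfreq_coding_snvs per-sample mean count of coding variants
#'   with qualifying frequency in (1%, 5%).
#' @param mean_common_coding_snvs per-sample mean common (>= 5%) coding
#'   variant count.
#' @param mean_rare_splice,mean_lowfreq_splice per-sample mean counts of
#'   noncoding splice-disrupting variants (delta >= 0.8) in the rare and
#'   additional low-frequency strata.
#' @param mean_noncoding_other per-sample mean sub-threshold noncoding
#'   variants (exercise the splice filter's rejections).
#' @param mean_rare_cnvs per-sample mean rare non-primary coding CNV count.
#' @param mean_common_cnvs per-sample mean common (non-rare) CNV count.
#' @param class_mixture named proportions over coding classes
#'   `lof`, `missense`, `synonymous`, `nonframeshift_indel` (sum 1).
#' @param qc_fail_rate fraction of variants drawn to fail genotype QC.
#' @param novel_rate fraction of rare variants absent from all three
#'   frequency databases.
#' @param db_missing_rate per-database missing probability for present
#'   frequencies.
#' @param prediction_shape Beta(a, b) shape for the per-missense-variant
#'   damaging-vote probability.
#' @param prediction_absent_rate per-predictor absent probability.
#' @param prop_asd expected fraction of the cohort in the ASD group.
#' @param age_range assessment age range in years.
#' @param score_params list of per-group means/SDs for `gca`, `broadind`,
#'   `css`.
#' @param poo_probs probabilities of maternal / paternal / unknown
#'   parent-of-origin.
#' @param effects list of injected burden-phenotype effects, each
#'   `list(gene_set =, outcome =, spec = burden_spec(...), slope =)`.
#'   Continuous outcomes are shifted additively by `slope * burden`;
#'   the binary group outcome by `slope` per unit burden on the log-odds
#'   scale (centred so the group balance is preserved).
#' @param dup7_region primary-locus region (list `chrom, start, end`).
#' @param dup7_size_mean,dup7_size_sd primary CNV size distribution (bp).
#' @param n_genes size of the synthetic gene universe.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 20, seed = 1,
                              mean_rare_coding_snvs = 185,
                              mean_lowfreq_coding_snvs = 60,
                              mean_common_coding_snvs = 30,
                              mean_rare_splice = 1.45,
                              mean_lowfreq_splice = 0.85,
                              mean_noncoding_other = 10,
                              mean_rare_cnvs = 35.4,
                              mean_common_cnvs = 5,
                              class_mixture = c(lof = 0.05, missense = 0.50,
                                                synonymous = 0.35,
                                                nonframeshift_indel = 0.10),
                              qc_fail_rate = 0.05,
                              novel_rate = 0.35,
                              db_missing_rate = 0.10,
                              prediction_shape = c(2, 2),
                              prediction_absent_rate = 0.05,
                              prop_asd = 0.45,
                              age_range = c(4, 17),
                              score_params = list(
                                gca = list(ASD = c(72, 10), non_ASD = c(78, 10)),
                                broadind = list(ASD = c(70, 10),
                                                non_ASD = c(85, 10)),
                                css = list(ASD = c(7, 1.5), non_ASD = c(2, 1))),
                              poo_probs = c(maternal = 0.45, paternal = 0.45,
                                            unknown = 0.10),
                              effects = list(),
                              dup7_region = .DUP7_REGION,
                              dup7_size_mean = 1.6e6,
                              dup7_size_sd = 1.2e5,
                              n_genes = 5000) {
  stopifnot(n_samples >= 6,
            abs(sum(class_mixture) - 1) < 1e-8,
            all(vapply(effects, function(e) is.finite(e$slope), TRUE)))
  structure(as.list(environment()), class = "simulation_config")
}

#' Synthetic gene models
#'
#' A deterministic gene universe: genes laid out on a 100 kb grid (50 kb
#' wide) across chromosomes chr1-chr22 and chrX, with the primary-locus
#' region on chr7 left gene-dense so CNV-overlap logic is exercised there
#' too.
#'
#' @param n_genes number of genes.
#' @return data frame `gene, chrom, start, end`.
#' @export
make_gene_models <- function(n_genes = 5000) {
  chroms <- c(paste0("chr", 1:22), "chrX")
  chrom <- chroms[(seq_len(n_genes) - 1L) %% length(chroms) + 1L]
  slot <- (seq_len(n_genes) - 1L) %/% length(chroms)
  start <- 1000001L + slot * 100000L
  data.frame(gene = sprintf("G%04d", seq_len(n_genes)), chrom = chrom,
             start = start, end = start + 49999L,
             stringsAsFactors = FALSE)
}

## standard synthetic gene-set collections; sizes span the GO/KEGG bounds
## so the size filter has work to do
.make_gene_sets <- function(genes) {
  spec <- list(
    list("NEUROSET_synaptic_signaling", "neuroset", 1500),
    list("NEUROSET_nervous_system_dev", "neuroset", 800),
    list("NEUROSET_brain_prenatal_expr", "neuroset", 400),
    list("NEUROSET_brain_low_expr", "neuroset", 200),
    list("NEUROSET_genic_intolerance_low", "neuroset", 120),
    list("NEUROSET_ion_channel", "neuroset", 60),
    list("ASD_risk_combined", "ASD_risk", 1132),
    list("GO_membrane_component", "GO", 600),
    list("GO_side_of_membrane", "GO", 150),
    list("GO_synapse_organization", "GO", 300),
    list("GO_small_undersized", "GO", 42),
    list("GO_oversized", "GO", 1200),
    list("KEGG_axon_guidance", "KEGG", 180),
    list("KEGG_synaptic_vesicle", "KEGG", 250),
    list("KEGG_tiny_undersized", "KEGG", 80))
  sets <- lapply(spec, function(s)
    list(name = s[[1]], category = s[[2]],
         genes = sample(genes, min(s[[3]], length(genes)))))
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

.draw_frequencies <- function(n, stratum, novel_rate, db_missing_rate) {
  out <- matrix(NA_real_, n, 3)
  if (!n) return(out)
  if (stratum == "rare") {
    f <- stats::runif(n, 0, 0.01)
    novel <- stats::runif(n) < novel_rate
    for (j in 1:3) {
      present <- stats::runif(n) >= db_missing_rate & !novel
      out[present, j] <- f[present] * stats::runif(sum(present), 0.5, 1)
    }
    carrier <- sample.int(3, n, replace = TRUE)
    idx <- which(!novel)
    out[cbind(idx, carrier[idx])] <- f[idx]    # max across dbs = f <= 1%
  } else if (stratum == "lowfreq") {
    f <- stats::runif(n, 0.0101, 0.0499)
    for (j in 1:3) {
      present <- stats::runif(n) >= db_missing_rate
      out[present, j] <- f[present] * stats::runif(sum(present), 0.5, 1)
    }
    carrier <- sample.int(3, n, replace = TRUE)
    out[cbind(seq_len(n), carrier)] <- f       # max in (1%, 5%)
  } else {
    f <- stats::runif(n, 0.05, 0.5)
    for (j in 1:3) {
      present <- stats::runif(n) >= db_missing_rate
      out[present, j] <- f[present] * stats::runif(sum(present), 0.9, 1)
    }
    carrier <- sample.int(3, n, replace = TRUE)
    out[cbind(seq_len(n), carrier)] <- f       # max >= 5%
  }
  out
}

## one block of variant rows for a (stratum x coding/noncoding) draw
.draw_variant_block <- function(cfg, gene_models, sample_ids, stratum,
                                kind, mean_count) {
  counts <- stats::rpois(length(sample_ids), mean_count)
  n <- sum(counts)
  if (!n) return(NULL)
  sid <- rep(sample_ids, counts)
  gi <- sample.int(nrow(gene_models), n, replace = TRUE)
  pos <- gene_models$start[gi] +
    sample.int(50000L, n, replace = TRUE) - 1L
  if (kind == "coding") {
    effect <- sample(names(cfg$class_mixture), n, replace = TRUE,
                     prob = cfg$class_mixture)
    lof_sub <- effect == "lof"
    effect[lof_sub] <- sample(c("nonsense", "frameshift_indel",
                                "core_splice_site"),
                              sum(lof_sub), replace = TRUE,
                              prob = c(0.5, 0.35, 0.15))
    region <- ifelse(effect == "core_splice_site", "splicing", "exonic")
    splice <- matrix(NA_real_, n, 4)
  } else if (kind == "splice") {
    effect <- rep("noncoding_other", n)
    region <- rep("intronic", n)
    splice <- matrix(stats::runif(n * 4, 0, 0.3), n, 4)
    hit <- sample.int(4, n, replace = TRUE)
    splice[cbind(seq_len(n), hit)] <- stats::runif(n, 0.8, 1)
  } else {  # sub-threshold noncoding
    effect <- rep("noncoding_other", n)
    region <- sample(c("intronic", "intergenic"), n, replace = TRUE,
                     prob = c(0.7, 0.3))
    splice <- matrix(stats::runif(n * 4, 0, 0.79), n, 4)
    splice[stats::runif(n * 4) < 0.3] <- NA
  }
  zyg <- ifelse(stats::runif(n) < 0.95, "het", "hom")
  gq <- ifelse(zyg == "het", 99, sample(25:99, n, replace = TRUE))
  aaf <- ifelse(zyg == "het", stats::runif(n, 0.3, 0.7),
                stats::runif(n, 0.71, 1))
  fail <- stats::runif(n) < cfg$qc_fail_rate
  fail_mode <- stats::runif(n)
  gq[fail & fail_mode < 0.5 & zyg == "het"] <-
    sample(40:98, sum(fail & fail_mode < 0.5 & zyg == "het"), replace = TRUE)
  gq[fail & fail_mode < 0.5 & zyg == "hom"] <-
    sample(1:24, sum(fail & fail_mode < 0.5 & zyg == "hom"), replace = TRUE)
  aaf[fail & fail_mode >= 0.5 & zyg == "het"] <-
    stats::runif(sum(fail & fail_mode >= 0.5 & zyg == "het"), 0.05, 0.29)
  aaf[fail & fail_mode >= 0.5 & zyg == "hom"] <-
    stats::runif(sum(fail & fail_mode >= 0.5 & zyg == "hom"), 0.3, 0.7)
  freqs <- .draw_frequencies(n, stratum, cfg$novel_rate,
                             cfg$db_missing_rate)
  bases <- c("A", "C", "G", "T")
  ri <- sample.int(4, n, replace = TRUE)
  ref <- bases[ri]
  alt <- bases[(ri + sample.int(3, n, replace = TRUE) - 1L) %% 4L + 1L]
  indel <- effect %in% c("frameshift_indel", "nonframeshift_indel")
  alt[indel] <- paste0(ref[indel], "A")
  d <- data.frame(sample_id = sid, chrom = gene_models$chrom[gi],
                  pos = pos, ref = ref, alt = alt, zygosity = zyg,
                  gq = gq, aaf = round(aaf, 3), effect = effect,
                  region = region, gene = gene_models$gene[gi],
                  stringsAsFactors = FALSE)
  d[.FREQ_COLS] <- round(freqs, 5)
  pd <- stats::rbeta(n, cfg$prediction_shape[1], cfg$prediction_shape[2])
  for (k in seq_len(8)) {
    v <- ifelse(stats::runif(n) < pd, "damaging", "benign")
    v[stats::runif(n) < cfg$prediction_absent_rate] <- NA
    v[effect != "missense"] <- NA
    d[[.PRED_COLS[k]]] <- v
  }
  d[.SPLICE_COLS] <- round(splice, 3)
  d$passed_caller_filters <- stats::runif(n) >= 0.01
  d
}

.draw_cnvs <- function(cfg, gene_models, sample_ids) {
  # primary duplication per sample
  size <- pmax(round(stats::rnorm(length(sample_ids), cfg$dup7_size_mean,
                                  cfg$dup7_size_sd)), 1200000)
  start <- cfg$dup7_region$start - sample.int(20000L, length(sample_ids),
                                              replace = TRUE)
  prim <- data.frame(sample_id = sample_ids, chrom = cfg$dup7_region$chrom,
                     start = as.integer(start),
                     end = as.integer(start + size - 1L),
                     cnv_type = "DUP", genes = "", is_rare = TRUE,
                     category = "pathogenic", stringsAsFactors = FALSE)
  draw_extra <- function(mean_count, rare) {
    counts <- stats::rpois(length(sample_ids), mean_count)
    n <- sum(counts)
    if (!n) return(prim[0, ])
    gi <- sample.int(nrow(gene_models), n, replace = TRUE)
    size <- as.integer(round(exp(stats::runif(n, log(5e3), log(5e5)))))
    # anchored to overlap the drawn gene: these emulate coding-impacting CNVs
    start <- pmax(1L, gene_models$start[gi] -
                    sample.int(4000L, n, replace = TRUE))
    data.frame(sample_id = rep(sample_ids, counts),
               chrom = gene_models$chrom[gi], start = start,
               end = start + size - 1L,
               cnv_type = sample(c("DEL", "DUP"), n, replace = TRUE),
               genes = "", is_rare = rare,
               category = if (rare) "VUS" else "benign",
               stringsAsFactors = FALSE)
  }
  cnvs <- rbind(prim, draw_extra(cfg$mean_rare_cnvs, TRUE),
                draw_extra(cfg$mean_common_cnvs, FALSE))
  # gene overlap on the deterministic grid (genes every 100 kb, 50 kb wide,
  # one chromosome-interleaved index per slot)
  chroms <- c(paste0("chr", 1:22), "chrX")
  ci <- match(cnvs$chrom, chroms)
  n_genes <- nrow(gene_models)
  cnvs$genes <- vapply(seq_len(nrow(cnvs)), function(i) {
    if (is.na(ci[i])) return("")
    lo <- max(0L, ceiling((cnvs$start[i] - 1000001L - 49999L) / 100000))
    hi <- floor((cnvs$end[i] - 1000001L) / 100000)
    if (hi < lo) return("")
    idx <- ci[i] + (lo:hi) * length(chroms)
    idx <- idx[idx >= 1 & idx <= n_genes]
    g <- gene_models$gene[idx]
    ok <- gene_models$start[idx] <= cnvs$end[i] &
      gene_models$end[idx] >= cnvs$start[i]
    paste(g[ok], collapse = ",")
  }, "")
  rownames(cnvs) <- NULL
  cnvs
}

#' Generate a synthetic cohort
#'
#' Draws gene sets, per-sample variants (coding strata at the configured
#' rare / low-frequency / common rates, splice-disrupting and sub-threshold
#' noncoding variants), CNVs (one primary duplication per sample plus rare
#' and common background CNVs), and phenotypes. Injected effects shift the
#' named outcome by `slope` per unit of the sample's qualifying burden in
#' the named gene set (additively for continuous scores, on the log-odds
#' scale for the binary group outcome), computed on the QC-passing variants
#' exactly as the analysis pipeline will measure it. The generated cohort
#' is a deterministic function of the configuration (including its seed).
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_cohort` with elements `variants`,
#'   `cnvs`, `phenotypes`, `gene_sets`, `gene_models`, `truth` (data frame
#'   of injected effects), and `config`.
#' @export
generate_cohort <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  gene_models <- make_gene_models(cfg$n_genes)
  gene_sets <- .make_gene_sets(gene_models$gene)
  for (e in cfg$effects)
    if (!e$gene_set %in% names(gene_sets))
      stop("injected effect names an unknown gene set: ", e$gene_set)
  sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))

  blocks <- list(
    .draw_variant_block(cfg, gene_models, sample_ids, "rare", "coding",
                        cfg$mean_rare_coding_snvs),
    .draw_variant_block(cfg, gene_models, sample_ids, "lowfreq", "coding",
                        cfg$mean_lowfreq_coding_snvs),
    .draw_variant_block(cfg, gene_models, sample_ids, "common", "coding",
                        cfg$mean_common_coding_snvs),
    .draw_variant_block(cfg, gene_models, sample_ids, "rare", "splice",
                        cfg$mean_rare_splice),
    .draw_variant_block(cfg, gene_models, sample_ids, "lowfreq", "splice",
                        cfg$mean_lowfreq_splice),
    .draw_variant_block(cfg, gene_models, sample_ids, "rare", "noncoding",
                        cfg$mean_noncoding_other))
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks)) stop("configuration generated no variants")
  variants <- do.call(rbind, blocks)
  rownames(variants) <- NULL

  cnvs <- .draw_cnvs(cfg, gene_models, sample_ids)

  n <- cfg$n_samples
  sex <- sample(c("M", "F"), n, replace = TRUE)
  age <- round(stats::runif(n, cfg$age_range[1], cfg$age_range[2]), 1)
  poo <- sample(names(cfg$poo_probs), n, replace = TRUE,
                prob = cfg$poo_probs)
  phen0 <- data.frame(sample_id = sample_ids, group = "non_ASD", sex = sex,
                      age = age, gca = NA_real_, broadind = NA_real_,
                      css = NA_real_, parent_of_origin = poo,
                      stringsAsFactors = FALSE)

  # burdens the pipeline will see: QC-passed variants only
  qc_variants <- variants[passes_genotype_qc(variants), , drop = FALSE]
  eff_burden <- lapply(cfg$effects, function(e)
    compute_burden(qc_variants, cnvs, phen0, e$spec,
                   gene_set = gene_sets[[e$gene_set]],
                   primary_region = cfg$dup7_region)$count)

  # binary group: baseline log-odds from prop_asd, plus centred injections
  eta <- rep(stats::qlogis(cfg$prop_asd), n)
  for (i in seq_along(cfg$effects)) {
    e <- cfg$effects[[i]]
    if (e$outcome == "group")
      eta <- eta + e$slope * (eff_burden[[i]] - mean(eff_burden[[i]]))
  }
  group <- ifelse(stats::runif(n) < stats::plogis(eta), "ASD", "non_ASD")
  phen0$group <- group

  draw_score <- function(name) {
    p <- cfg$score_params[[name]]
    mu <- ifelse(group == "ASD", p$ASD[1], p$non_ASD[1])
    sdv <- ifelse(group == "ASD", p$ASD[2], p$non_ASD[2])
    stats::rnorm(n, mu, sdv)
  }
  gca <- draw_score("gca")
  broadind <- draw_score("broadind")
  css <- draw_score("css")
  for (i in seq_along(cfg$effects)) {
    e <- cfg$effects[[i]]
    if (e$outcome == "gca") gca <- gca + e$slope * eff_burden[[i]]
    if (e$outcome == "broadind")
      broadind <- broadind + e$slope * eff_burden[[i]]
    if (e$outcome == "css") css <- css + e$slope * eff_burden[[i]]
  }
  phen0$gca <- round(gca, 1)
  phen0$broadind <- round(broadind, 1)
  phen0$css <- pmin(10L, pmax(1L, as.integer(round(css))))

  truth <- if (length(cfg$effects)) do.call(rbind, lapply(
    seq_along(cfg$effects), function(i) {
      e <- cfg$effects[[i]]
      data.frame(gene_set = e$gene_set, outcome = e$outcome,
                 variant_class = e$spec$variant_class,
                 frequency_level = e$spec$frequency_level,
                 slope = e$slope,
                 mean_burden = mean(eff_burden[[i]]),
                 stringsAsFactors = FALSE)
    })) else
      data.frame(gene_set = character(), outcome = character(),
                 variant_class = character(), frequency_level = numeric(),
                 slope = numeric(), mean_burden = numeric(),
                 stringsAsFactors = FALSE)

  structure(list(variants = variants, cnvs = cnvs, phenotypes = phen0,
                 gene_sets = gene_sets, gene_models = gene_models,
                 truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the flat-file dialects read back by the formats module: a variant
#' table, CNV table, phenotype table, gene-set GMT, gene-model table, and
#' a truth manifest of injected effects.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_variants(cohort$variants, file.path(dir, "variants.tsv"))
  write_cnvs(cohort$cnvs, file.path(dir, "cnvs.tsv"))
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_gene_sets(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  utils::write.table(cohort$gene_models, file.path(dir, "gene_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a written cohort back from disk
#'
#' @param dir a directory produced by [write_cohort()].
#' @return list with `variants`, `cnvs`, `phenotypes`, `gene_sets`.
#' @export
read_cohort <- function(dir) {
  list(variants = read_variants(file.path(dir, "variants.tsv")),
       cnvs = read_cnvs(file.path(dir, "cnvs.tsv")),
       phenotypes = read_phenotypes(file.path(dir, "phenotypes.tsv")),
       gene_sets = read_gene_sets(file.path(dir, "gene_sets.gmt"),
                                  category_map = NULL))
}
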