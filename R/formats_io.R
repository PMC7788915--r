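## formats_io: readers/writers for the flat-file dialects and VCF, plus
## normalization into the package's internal tables.

#' Read annotated small-variant calls
#'
#' Reads per-sample annotated variant calls from either the package's flat
#' tab-separated dialect or an annotated VCF, and normalizes them to the
#' internal variant table (see [dup7burden-package]). Multi-allelic VCF
#' records are decomposed into one row per alternate allele; structurally
#' unparseable rows are skipped with a message reporting the count.
#'
#' @param path path to the input file.
#' @param dialect `"table"` (tab-separated with header; default) or `"vcf"`.
#' @param field_map for the VCF dialect, a named list mapping internal
#'   fields to INFO/FORMAT keys; see [default_vcf_field_map()].
#' @return a variant data frame with the columns documented in
#'   [dup7burden-package].
#' @export
read_variants <- function(path, dialect = c("table", "vcf"),
                          field_map = default_vcf_field_map()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("variant file not found: ", path)
  if (dialect == "table") read_variants_table(path) else
    read_variants_vcf(path, field_map)
}

read_variants_table <- function(path) {
  # colClasses = "character": allele strings like "T" must not become
  # logicals; numeric columns are coerced explicitly below
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", ""))
  missing <- setdiff(.VARIANT_COLS, names(raw))
  if (length(missing))
    stop("variant table is missing required column(s): ",
         paste(missing, collapse = ", "))
  raw <- raw[, .VARIANT_COLS]
  raw$pos <- as.integer(raw$pos)
  raw$gq <- as.numeric(raw$gq)
  raw$aaf <- as.numeric(raw$aaf)
  for (cl in c(.FREQ_COLS, .SPLICE_COLS)) raw[[cl]] <- as.numeric(raw[[cl]])
  raw$passed_caller_filters <- as.logical(raw$passed_caller_filters)
  raw$gene[is.na(raw$gene)] <- ""
  ok <- !is.na(raw$pos) & raw$pos >= 1 &
    !is.na(raw$aaf) & raw$aaf >= 0 & raw$aaf <= 1 &
    raw$zygosity %in% c("het", "hom") &
    raw$effect %in% .EFFECT_LEVELS &
    raw$region %in% .REGION_LEVELS &
    !is.na(raw$passed_caller_filters)
  for (cl in .FREQ_COLS)
    ok <- ok & (is.na(raw[[cl]]) | (raw[[cl]] >= 0 & raw[[cl]] <= 1))
  for (cl in .SPLICE_COLS)
    ok <- ok & (is.na(raw[[cl]]) | (raw[[cl]] >= 0 & raw[[cl]] <= 1))
  if (any(!ok))
    message("read_variants: skipped ", sum(!ok),
            " structurally invalid record(s)")
  out <- raw[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default VCF field mapping
#'
#' Maps the internal variant fields to the INFO/FORMAT keys the VCF reader
#' expects. `pred` must name an INFO key holding eight comma-separated
#' tri-state calls (`D` damaging, `B` benign, `.` absent) in the fixed
#' predictor order (CADD, SIFT, PolyPhen, Provean, MutationAssessor,
#' MutationTaster, PhyloPMam, PhyloPVert); `spliceai` an INFO key with four
#' comma-separated delta scores (acceptor gain/loss, donor gain/loss).
#' Frequency INFO fields are per-alternate-allele (Number=A).
#'
#' @return a named list of INFO/FORMAT key names.
#' @export
default_vcf_field_map <- function() {
  list(gene = "GENE", effect = "EFFECT", region = "REGION",
       freq_1kg = "AF_1KG", freq_exac = "AF_EXAC", freq_gnomad = "AF_GNOMAD",
       pred = "DMG", spliceai = "SPAI", gq = "GQ", aaf = "AAF")
}

.info_field <- function(info, key) {
  # returns character vector (NA where key absent)
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

.split_nth <- function(x, i, sep = ",") {
  # i-th comma-separated component of each element of x
  vapply(seq_along(x), function(j) {
    if (is.na(x[j])) return(NA_character_)
    parts <- strsplit(x[j], sep, fixed = TRUE)[[1]]
    if (i <= length(parts)) parts[i] else NA_character_
  }, "")
}

.num_or_na <- function(x) suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))

read_variants_vcf <- function(path, field_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm)))   # single-record files drop to a named vector
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  info <- vcfR::getINFO(v)
  gt_m <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_m)))
    gt_m <- matrix(gt_m, nrow = 1, dimnames = list(NULL, names(gt_m)))
  gq_m <- suppressWarnings(
    vcfR::extract.gt(v, element = field_map$gq, as.numeric = TRUE))
  aaf_m <- suppressWarnings(
    vcfR::extract.gt(v, element = field_map$aaf, as.numeric = TRUE))
  if (is.null(dim(gq_m)))
    gq_m <- matrix(gq_m, nrow = 1, dimnames = list(NULL, names(gq_m)))
  if (is.null(dim(aaf_m)))
    aaf_m <- matrix(aaf_m, nrow = 1, dimnames = list(NULL, names(aaf_m)))
  samples <- colnames(gt_m)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    eff <- .info_field(info[i], field_map$effect)
    reg <- .info_field(info[i], field_map$region)
    gene <- .info_field(info[i], field_map$gene)
    preds <- .info_field(info[i], field_map$pred)
    spai <- .info_field(info[i], field_map$spliceai)
    pred_v <- if (!is.na(preds))
      strsplit(preds, ",", fixed = TRUE)[[1]] else rep(".", 8)
    if (length(pred_v) != 8) { skipped <- skipped + 1L; next }
    spai_v <- if (!is.na(spai))
      .num_or_na(strsplit(spai, ",", fixed = TRUE)[[1]]) else rep(NA_real_, 4)
    if (length(spai_v) != 4) spai_v <- rep(NA_real_, 4)
    for (a in seq_along(alts)) {
      f1 <- .num_or_na(.split_nth(.info_field(info[i], field_map$freq_1kg), a))
      f2 <- .num_or_na(.split_nth(.info_field(info[i], field_map$freq_exac), a))
      f3 <- .num_or_na(.split_nth(.info_field(info[i], field_map$freq_gnomad), a))
      for (s in samples) {
        gt <- gt_m[i, s]
        if (is.na(gt)) next
        al <- strsplit(gt, "[/|]")[[1]]
        n_alt <- sum(al == as.character(a))
        if (n_alt == 0) next
        zyg <- if (n_alt >= 2) "hom" else "het"
        effv <- if (is.na(eff)) NA_character_ else eff
        regv <- if (is.na(reg)) "other" else reg
        if (is.na(effv) || !effv %in% .EFFECT_LEVELS ||
            !regv %in% .REGION_LEVELS) { skipped <- skipped + 1L; next }
        row <- data.frame(
          sample_id = s, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
          ref = fix$REF[i], alt = alts[a], zygosity = zyg,
          gq = gq_m[i, s], aaf = aaf_m[i, s],
          effect = effv, region = regv,
          gene = if (is.na(gene)) "" else gene,
          stringsAsFactors = FALSE)
        row[.FREQ_COLS] <- list(f1, f2, f3)
        for (k in seq_len(8))
          row[[.PRED_COLS[k]]] <- switch(pred_v[k], D = "damaging",
                                         B = "benign", NA_character_)
        for (k in seq_len(4)) row[[.SPLICE_COLS[k]]] <- spai_v[k]
        row$passed_caller_filters <- fix$FILTER[i] %in% c("PASS", ".")
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (skipped > 0)
    message("read_variants: skipped ", skipped,
            " structurally invalid record(s)")
  if (!length(rows)) {
    out <- utils::read.delim(text = paste(.VARIANT_COLS, collapse = "\t"))
    return(out[0, ])
  }
  out <- do.call(rbind, rows)[, .VARIANT_COLS]
  rownames(out) <- NULL
  out
}

#' Write a variant table
#'
#' Writes the flat tab-separated variant dialect; `read_variants()` on the
#' output reproduces the input records.
#'
#' @param variants a variant data frame.
#' @param path output path.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants[, .VARIANT_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene-set collections from a GMT file
#'
#' One gene set per line: name, description, then tab-separated gene
#' symbols. Duplicate symbols within a line are removed; lines with fewer
#' than three fields are skipped with a warning. The set category is taken
#' from `category_map[[name]]` when supplied, else from a `CATEGORY:`-style
#' name prefix (`GO`, `KEGG`, `NEUROSET`, `ASD`), else `default_category`.
#'
#' @param path path to a GMT file.
#' @param category_map optional named character vector mapping set names to
#'   categories (`ASD_risk`, `neuroset`, `GO`, `KEGG`).
#' @param default_category category used when no mapping or prefix applies.
#' @return a list of gene sets, each `list(name, category, genes)`.
#' @export
read_gene_sets <- function(path, category_map = NULL,
                           default_category = "neuroset") {
  if (!file.exists(path)) stop("gene-set file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      warning("read_gene_sets: skipping malformed line: ",
              substr(ln, 1, 40))
      next
    }
    name <- parts[1]
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    cat <- if (!is.null(category_map) && name %in% names(category_map))
      unname(category_map[name])
    else if (grepl("^GO[:_]", name)) "GO"
    else if (grepl("^KEGG[:_]", name)) "KEGG"
    else if (grepl("^ASD[:_]", name)) "ASD_risk"
    else if (grepl("^NEUROSET[:_]", name)) "neuroset"
    else default_category
    sets[[length(sets) + 1L]] <- list(name = name, category = cat,
                                      genes = genes)
  }
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a list of gene sets as returned by [read_gene_sets()].
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$category, s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read CNV calls
#'
#' The native dialect is tab-separated with 1-based inclusive `start`/`end`
#' coordinates (so size = end - start + 1). `dialect = "bed"` imports
#' half-open 0-based BED intervals by adding 1 to the start.
#'
#' @param path path to the CNV table.
#' @param dialect `"table"` (default) or `"bed"`.
#' @return a CNV data frame (see [dup7burden-package]).
#' @export
read_cnvs <- function(path, dialect = c("table", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("CNV file not found: ", path)
  if (dialect == "bed") {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(raw)[1:5] <- c("chrom", "start", "end", "sample_id", "cnv_type")
    raw$start <- as.integer(raw$start) + 1L   # 0-based half-open -> 1-based
    raw$end <- as.integer(raw$end)
    raw$genes <- ""
    raw$is_rare <- TRUE
    raw$category <- "unclassified"
    raw <- raw[, .CNV_COLS]
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
    missing <- setdiff(.CNV_COLS, names(raw))
    if (length(missing))
      stop("CNV table is missing required column(s): ",
           paste(missing, collapse = ", "))
    raw <- raw[, .CNV_COLS]
    raw$start <- as.integer(raw$start)
    raw$end <- as.integer(raw$end)
  }
  if (nrow(raw)) {
    raw$genes[is.na(raw$genes)] <- ""
    raw$is_rare <- as.logical(raw$is_rare)
    bad <- is.na(raw$start) | is.na(raw$end) | raw$end < raw$start |
      !raw$cnv_type %in% c("DEL", "DUP")
    if (any(bad))
      message("read_cnvs: skipped ", sum(bad), " invalid record(s)")
    raw <- raw[!bad, , drop = FALSE]
  }
  rownames(raw) <- NULL
  raw
}

#' Write CNV calls in the native 1-based inclusive dialect
#' @param cnvs a CNV data frame.
#' @param path output path.
#' @export
write_cnvs <- function(cnvs, path) {
  utils::write.table(cnvs[, .CNV_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read the phenotype table
#'
#' Tab-separated with header; columns `sample_id, group, sex, age, gca,
#' broadind, css, parent_of_origin`. Unknown group or sex labels are fatal.
#'
#' @param path path to the phenotype table.
#' @return a phenotype data frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  missing <- setdiff(.PHENO_COLS, names(raw))
  if (length(missing))
    stop("phenotype table is missing required column(s): ",
         paste(missing, collapse = ", "))
  raw <- raw[, .PHENO_COLS]
  bad_group <- !raw$group %in% c("ASD", "non_ASD")
  if (any(bad_group))
    stop("unknown group label(s): ",
         paste(unique(raw$group[bad_group]), collapse = ", "))
  bad_sex <- !raw$sex %in% c("M", "F")
  if (any(bad_sex))
    stop("unknown sex label(s): ",
         paste(unique(raw$sex[bad_sex]), collapse = ", "))
  raw$parent_of_origin[is.na(raw$parent_of_origin)] <- "unknown"
  bad_poo <- !raw$parent_of_origin %in% c("maternal", "paternal", "unknown")
  if (any(bad_poo))
    stop("unknown parent_of_origin label(s): ",
         paste(unique(raw$parent_of_origin[bad_poo]), collapse = ", "))
  if (any(!is.na(raw$css) & (raw$css < 1 | raw$css > 10)))
    stop("css outside [1,10]")
  if (any(!is.na(raw$age) & raw$age <= 0)) stop("age must be positive")
  rownames(raw) <- NULL
  raw
}

#' Write the phenotype table
#' @param phenotypes a phenotype data frame.
#' @param path output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes[, .PHENO_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write an association-results table
#'
#' Tab-separated report mirroring the hits-table layout: outcome, burden
#' variable, pathway category, pathway, gene and variant tallies, raw
#' coefficient, one-tailed P, FDR.
#'
#' @param results an association-results data frame (see
#'   [fit_outcome_model()] / [run_pathway_scan()]).
#' @param path output path.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
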