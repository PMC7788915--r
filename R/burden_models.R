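## burden_models: per-sample burden variables, covariate-adjusted
## regression with one-tailed directional inference, FDR control, control
## models, and the significance gate.

#' Define a burden variable
#'
#' A burden specification names a countable variant class and frequency
#' level. `mis_k` (number of damaging prediction votes required) applies
#' only to the missense class; `include_splice` folds splice-filter-passing
#' variants into the LoF class.
#'
#' @param variant_class one of `lof_snv`, `missense_snv`, `cnv_non_primary`,
#'   `synonymous_snv`, `nonframeshift_indel` (the last two are the control
#'   classes).
#' @param frequency_level 0.01 (rare) or 0.05 (low frequency).
#' @param mis_k damaging-vote threshold for missense (default 4; must be
#'   `NULL` for other classes).
#' @param include_splice include splice-disrupting variants in LoF counts?
#' @return a `burden_spec` list.
#' @export
burden_spec <- function(variant_class = c("lof_snv", "missense_snv",
                                          "cnv_non_primary", "synonymous_snv",
                                          "nonframeshift_indel"),
                        frequency_level = 0.01, mis_k = NULL,
                        include_splice = FALSE) {
  variant_class <- match.arg(variant_class)
  stopifnot(frequency_level %in% c(0.01, 0.05))
  if (variant_class == "missense_snv") {
    if (is.null(mis_k)) mis_k <- 4L
    stopifnot(mis_k >= 1, mis_k <= 8)
  } else if (!is.null(mis_k)) {
    stop("mis_k applies only to the missense_snv class")
  }
  structure(list(variant_class = variant_class,
                 frequency_level = frequency_level,
                 mis_k = if (is.null(mis_k)) NA_integer_ else as.integer(mis_k),
                 include_splice = isTRUE(include_splice)),
            class = "burden_spec")
}

#' @export
format.burden_spec <- function(x, ...) {
  lbl <- paste0(x$variant_class, " (", x$frequency_level * 100, "%")
  if (!is.na(x$mis_k)) lbl <- paste0(lbl, ", mis_", x$mis_k)
  if (x$include_splice) lbl <- paste0(lbl, ", +splice")
  paste0(lbl, ")")
}

#' @export
print.burden_spec <- function(x, ...) cat(format(x), "\n")

## logical mask of variants qualifying under a spec (SNV classes only)
.qualifying_snv <- function(variants, spec, splice_threshold = 0.8) {
  tier <- frequency_tier(variants, spec$frequency_level)
  cls_mask <- switch(
    spec$variant_class,
    lof_snv = functional_class(variants, spec$include_splice,
                               splice_threshold) == "lof",
    missense_snv = variants$effect == "missense" &
      damaging_vote_count(variants) >= spec$mis_k,
    synonymous_snv = variants$effect == "synonymous",
    nonframeshift_indel = variants$effect == "nonframeshift_indel",
    stop("not an SNV class: ", spec$variant_class))
  tier & cls_mask
}

#' Per-sample burden counts
#'
#' Counts, per sample, the variants qualifying under a burden
#' specification: LoF / missense / control SNV classes at the requested
#' frequency level, or rare CNVs outside the primary locus. Variants are
#' assumed to have passed genotype QC already. Samples with no qualifying
#' variants get a count of 0; a variant carried by a sample absent from the
#' phenotype table is a cohort mismatch and fatal.
#'
#' @param variants QC-passed variant data frame.
#' @param cnvs CNV data frame (used only for the CNV class).
#' @param phenotypes phenotype data frame defining the cohort.
#' @param spec a [burden_spec()].
#' @param gene_set optional gene set (`list(name, category, genes)`)
#'   restricting the count to variants in member genes; CNVs count once per
#'   sample when any overlapped gene is a member.
#' @param splice_threshold delta-score threshold for splice inclusion.
#' @param primary_region primary-locus region for CNV exclusion.
#' @return data frame `sample_id, count` in phenotype-table order, with
#'   attributes `spec`, `gene_set`, `n_genes`, `n_variants_observed`.
#' @export
compute_burden <- function(variants, cnvs, phenotypes, spec,
                           gene_set = NULL, splice_threshold = 0.8,
                           primary_region = .DUP7_REGION) {
  samples <- phenotypes$sample_id
  if (spec$variant_class == "cnv_non_primary") {
    keep <- cnvs$is_rare & !is_primary_locus(cnvs, primary_region)
    sub <- cnvs[keep, , drop = FALSE]
    if (!is.null(gene_set)) {
      gl <- strsplit(sub$genes, ",", fixed = TRUE)
      hit <- vapply(gl, function(g) any(g %in% gene_set$genes), TRUE)
      sub <- sub[hit, , drop = FALSE]
    }
  } else {
    keep <- .qualifying_snv(variants, spec, splice_threshold)
    sub <- variants[keep, , drop = FALSE]
    if (!is.null(gene_set))
      sub <- sub[sub$gene %in% gene_set$genes, , drop = FALSE]
  }
  extra <- setdiff(unique(sub$sample_id), samples)
  if (length(extra))
    stop("cohort mismatch: variant sample(s) absent from phenotype table: ",
         paste(extra, collapse = ", "))
  counts <- table(factor(sub$sample_id, levels = samples))
  out <- data.frame(sample_id = samples, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  attr(out, "gene_set") <- if (is.null(gene_set)) NA_character_ else
    gene_set$name
  attr(out, "n_genes") <- if (is.null(gene_set)) NA_integer_ else
    length(gene_set$genes)
  attr(out, "n_variants_observed") <- nrow(sub)
  out
}

#' Required coefficient sign per outcome
#'
#' Deleterious burden is expected to increase the odds of the affected
#' group and the symptom severity score, and to decrease the intellectual
#' ability and adaptive behaviour standard scores; one-tailed tests are
#' taken in those directions.
#'
#' @return named numeric vector of required signs (+1 / -1) for outcomes
#'   `group`, `css`, `gca`, `broadind`.
#' @export
default_sign_convention <- function() {
  c(group = 1, css = 1, gca = -1, broadind = -1)
}

#' Convert a two-sided p-value to the directional one-tailed p
#'
#' If the fitted coefficient's sign matches the required direction for the
#' outcome, the one-tailed p is half the two-sided p; otherwise it is
#' 1 - p/2. A zero coefficient gives 0.5.
#'
#' @param p_two_sided two-sided p-value(s) in (0, 1].
#' @param B fitted raw coefficient(s).
#' @param outcome outcome name(s).
#' @param convention a sign convention as from [default_sign_convention()].
#' @return one-tailed p-value(s).
#' @export
one_tailed_p <- function(p_two_sided, B, outcome,
                         convention = default_sign_convention()) {
  req <- convention[outcome]
  out <- ifelse(B == 0, 0.5,
                ifelse(sign(B) == req, p_two_sided / 2, 1 - p_two_sided / 2))
  unname(out)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values: q_(i) = min over j >= i of m * p_(j) / j, capped at 1.
#'
#' @param p p-values in (0, 1].
#' @return q-values in input order; empty input gives empty output.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

.empty_result <- function() {
  data.frame(outcome = character(), variant_class = character(),
             frequency_level = numeric(), mis_k = integer(),
             include_splice = logical(), gene_set = character(),
             category = character(), n_genes = integer(),
             n_variants_observed = integer(), n_samples = integer(),
             coefficient_B = numeric(), p_two_sided = numeric(),
             p_one_tailed = numeric(), fdr = numeric(),
             converged = logical(), control = logical(),
             stringsAsFactors = FALSE)
}

#' Fit one covariate-adjusted burden model
#'
#' Fits `logit(outcome) = sex + age + burden` (maximum-likelihood logistic
#' regression) for the binary group outcome, or
#' `outcome = sex + age + burden` (ordinary least squares) for the
#' continuous scores. The burden coefficient's two-sided Wald p-value is
#' converted to the directional one-tailed p via [one_tailed_p()]. Sex is
#' coded 0/1 with F as reference; age is continuous in years; neither is
#' standardized. Samples missing the outcome are dropped with a message.
#' Zero-variance burden, non-convergence, and (for the logistic model)
#' perfect or quasi-perfect separation yield `converged = FALSE`; a Firth-
#' style penalized fallback is deliberately not applied unless requested.
#'
#' @param burden a burden matrix from [compute_burden()].
#' @param phenotypes phenotype data frame.
#' @param outcome one of `group`, `gca`, `broadind`, `css`.
#' @param convention sign convention for the one-tailed conversion.
#' @param penalized use a ridge-penalized logistic fallback on separation?
#'   Off by default; separation is reported, not silently repaired.
#' @return one-row association-results data frame (`fdr` is `NA`; families
#'   are adjusted jointly by the scan drivers).
#' @export
fit_outcome_model <- function(burden, phenotypes,
                              outcome = c("group", "gca", "broadind", "css"),
                              convention = default_sign_convention(),
                              penalized = FALSE) {
  outcome <- match.arg(outcome)
  spec <- attr(burden, "spec")
  d <- merge(burden, phenotypes, by = "sample_id", sort = FALSE)
  d$sex01 <- as.integer(d$sex == "M")
  y <- if (outcome == "group") as.integer(d$group == "ASD") else d[[outcome]]
  keep <- !is.na(y)
  if (any(!keep))
    message("fit_outcome_model: dropping ", sum(!keep),
            " sample(s) with missing ", outcome)
  d <- d[keep, , drop = FALSE]; y <- y[keep]
  res <- data.frame(
    outcome = outcome,
    variant_class = spec$variant_class,
    frequency_level = spec$frequency_level,
    mis_k = spec$mis_k,
    include_splice = spec$include_splice,
    gene_set = attr(burden, "gene_set"),
    category = NA_character_,
    n_genes = attr(burden, "n_genes"),
    n_variants_observed = attr(burden, "n_variants_observed"),
    n_samples = length(y),
    coefficient_B = NA_real_, p_two_sided = NA_real_,
    p_one_tailed = NA_real_, fdr = NA_real_,
    converged = FALSE, control = FALSE,
    stringsAsFactors = FALSE)
  if (length(y) < 6 || stats::sd(d$count) == 0 ||
      (outcome == "group" && length(unique(y)) < 2))
    return(res)
  if (outcome == "group") {
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ sex01 + age + count, family = stats::binomial(),
                 data = d),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (!fit$converged || sep_warn) {
      if (!penalized) {
        message("fit_outcome_model: logistic fit did not converge cleanly ",
                "(possible separation); result flagged non-converged")
        return(res)
      }
      fit <- .ridge_logit(y, d)
    }
    sm <- summary(fit)$coefficients
  } else {
    fit <- stats::lm(y ~ sex01 + age + count, data = d)
    sm <- summary(fit)$coefficients
  }
  if (!"count" %in% rownames(sm) || is.na(sm["count", 2])) return(res)
  B <- sm["count", 1]
  p2 <- sm["count", 4]
  res$coefficient_B <- B
  res$p_two_sided <- p2
  res$p_one_tailed <- one_tailed_p(p2, B, outcome, convention)
  res$converged <- TRUE
  res
}

## weak ridge penalty on the burden coefficient; used only when explicitly
## requested for separated logistic fits
.ridge_logit <- function(y, d) {
  X <- cbind(1, d$sex01, d$age, d$count)
  colnames(X) <- c("(Intercept)", "sex01", "age", "count")
  lambda <- 0.5
  b <- rep(0, 4)
  for (it in 1:100) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + diag(lambda, 4)
    g <- crossprod(X, y - mu) - lambda * b
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- drop(X %*% b)
  mu <- stats::plogis(eta)
  H <- crossprod(X, X * (mu * (1 - mu))) + diag(lambda, 4)
  se <- sqrt(diag(solve(H)))
  zs <- b / se
  fit <- list(converged = TRUE)
  cm <- cbind(b, se, zs, 2 * stats::pnorm(-abs(zs)))
  rownames(cm) <- colnames(X)
  structure(list(converged = TRUE, coefficients = b,
                 .cm = cm), class = "ridge_logit")
}

#' @export
summary.ridge_logit <- function(object, ...) list(coefficients = object$.cm)

#' Genome-wide burden analysis
#'
#' Fits every (outcome x burden spec) model and adjusts FDR within each
#' outcome's family of genome-wide models (converged models only).
#'
#' @param variants QC-passed variant data frame.
#' @param cnvs CNV data frame.
#' @param phenotypes phenotype data frame.
#' @param specs list of [burden_spec()]s; defaults to LoF, likely-damaging
#'   missense (4 of 8 votes) and non-primary CNV burdens at both frequency
#'   levels.
#' @param outcomes outcomes to model.
#' @param convention sign convention.
#' @param ... passed to [compute_burden()].
#' @return association-results data frame with `fdr` filled.
#' @export
run_burden_analysis <- function(variants, cnvs, phenotypes,
                                specs = default_burden_specs(),
                                outcomes = .OUTCOMES,
                                convention = default_sign_convention(),
                                ...) {
  rows <- list()
  for (sp in specs) {
    b <- compute_burden(variants, cnvs, phenotypes, sp, ...)
    for (oc in outcomes)
      rows[[length(rows) + 1L]] <-
        fit_outcome_model(b, phenotypes, oc, convention)
  }
  res <- if (length(rows)) do.call(rbind, rows) else .empty_result()
  adjust_fdr_families(res, family_keys = "outcome")
}

#' Default genome-wide burden specifications
#' @return list of [burden_spec()]s.
#' @export
default_burden_specs <- function() {
  list(burden_spec("lof_snv", 0.01), burden_spec("lof_snv", 0.05),
       burden_spec("missense_snv", 0.01, mis_k = 4),
       burden_spec("missense_snv", 0.05, mis_k = 4),
       burden_spec("cnv_non_primary", 0.01),
       burden_spec("cnv_non_primary", 0.05))
}

#' Control burden models
#'
#' Re-runs the association machinery with the synonymous and
#' non-frameshift-indel control classes (no direct functional effect
#' expected), to expose residual confounding. Control results are flagged
#' and FDR-adjusted in their own families; they never enter the primary
#' family.
#'
#' @inheritParams run_burden_analysis
#' @param frequency_levels levels at which to build control burdens.
#' @return association-results data frame with `control = TRUE`.
#' @export
run_control_models <- function(variants, cnvs, phenotypes,
                               frequency_levels = c(0.01, 0.05),
                               outcomes = .OUTCOMES,
                               convention = default_sign_convention(),
                               ...) {
  specs <- list()
  for (lv in frequency_levels) {
    specs[[length(specs) + 1L]] <- burden_spec("synonymous_snv", lv)
    specs[[length(specs) + 1L]] <- burden_spec("nonframeshift_indel", lv)
  }
  res <- run_burden_analysis(variants, cnvs, phenotypes, specs, outcomes,
                             convention, ...)
  res$control <- TRUE
  res
}

#' Adjust FDR within families
#'
#' Computes Benjamini-Hochberg q-values jointly over the converged models
#' of each family, where a family is defined by the combination of the
#' given key columns. Non-converged models keep `fdr = NA` and do not
#' influence the family.
#'
#' @param results association-results data frame.
#' @param family_keys column names defining a family.
#' @return the results with `fdr` filled for converged rows.
#' @export
adjust_fdr_families <- function(results,
                                family_keys = c("outcome", "variant_class",
                                                "frequency_level", "mis_k",
                                                "include_splice", "category")) {
  if (!nrow(results)) return(results)
  keys <- results[, intersect(family_keys, names(results)), drop = FALSE]
  fam <- do.call(paste, c(lapply(keys, function(x) ifelse(is.na(x), ".", x)),
                          sep = "|"))
  results$fdr <- NA_real_
  for (f in unique(fam)) {
    idx <- which(fam == f & results$converged)
    if (length(idx)) results$fdr[idx] <- bh_fdr(results$p_one_tailed[idx])
  }
  results
}

#' Significance gate
#'
#' A converged model passes when (1) the raw coefficient's sign matches the
#' required direction for its outcome, (2) the one-tailed p-value is at
#' most `p_max`, and (3) the FDR is at most `fdr_max`. Bounds are
#' inclusive.
#'
#' @param results association-results data frame (or one row).
#' @param p_max one-tailed p cut-off (default 0.05).
#' @param fdr_max FDR cut-off (default 0.15).
#' @param convention sign convention.
#' @return logical vector, one element per row.
#' @export
significance_gate <- function(results, p_max = 0.05, fdr_max = 0.15,
                              convention = default_sign_convention()) {
  req <- convention[results$outcome]
  ok <- results$converged &
    sign(results$coefficient_B) == req &
    results$p_one_tailed <= p_max &
    results$fdr <= fdr_max
  ok & !is.na(ok)
}
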