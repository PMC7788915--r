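## cohort_stats: group contrasts of clinical scores, the parent-of-origin
## contingency test, and the primary-CNV size comparison.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups. For small samples
#' (nA + nB <= `exact_max`, default 12) the null distribution of U is
#' enumerated over all group assignments of the pooled values and the
#' two-sided p is the probability of a U at least as far from its mean as
#' observed. Otherwise the normal approximation with tie correction is
#' used, without continuity correction. U counts pairs where an A value
#' exceeds a B value, ties counting one half.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact_max largest pooled size for the exact branch.
#' @return list with `u`, `z`, `p_two_sided`, `method`, `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 12) {
  if (!length(a) || !length(b))
    stop("mann_whitney_u: both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx_a) sum(r[idx_a]) - length(idx_a) *
    (length(idx_a) + 1) / 2
  u_obs <- u_of(seq_len(na))
  mu <- na * nb / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- if (sigma2 > 0) (u_obs - mu) / sqrt(sigma2) else 0
  if (n <= exact_max) {
    combos <- utils::combn(n, na)
    us <- apply(combos, 2, u_of)
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
    method <- "normal"
  }
  list(u = u_obs, z = z, p_two_sided = min(p, 1), method = method,
       n_a = na, n_b = nb)
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p by the probability-mass rule: the sum of hypergeometric
#' probabilities (margins fixed) of all tables no more probable than the
#' observed one.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (sum(tab) == 0) stop("fisher_exact_2x2: all-zero table")
  stats::fisher.test(tab)$p.value
}

#' Parent-of-origin contingency table
#'
#' 2x2 counts of primary-CNV parent-of-origin by group; samples with
#' unknown origin are excluded.
#'
#' @param phenotypes phenotype data frame.
#' @return 2x2 matrix, rows ASD / non_ASD, columns maternal / paternal.
#' @export
parent_of_origin_table <- function(phenotypes) {
  known <- phenotypes[phenotypes$parent_of_origin %in%
                        c("maternal", "paternal"), , drop = FALSE]
  tab <- table(factor(known$group, levels = c("ASD", "non_ASD")),
               factor(known$parent_of_origin,
                      levels = c("maternal", "paternal")))
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(c("ASD", "non_ASD"),
                              c("maternal", "paternal")))
  m
}

#' Primary-CNV size summary and group comparison
#'
#' Sizes the primary-locus CNV of every sample (each sample must carry
#' exactly one), reports per-group mean and sample (n-1) standard
#' deviation, and compares the two groups with [mann_whitney_u()].
#'
#' @param cnvs CNV data frame.
#' @param phenotypes phenotype data frame.
#' @param primary_region primary-locus region (see [is_primary_locus()]).
#' @return list with `by_group` (data frame `group, n, mean_bp, sd_bp`) and
#'   `comparison` (a [mann_whitney_u()] result).
#' @export
summarize_dup7_sizes <- function(cnvs, phenotypes,
                                 primary_region = .DUP7_REGION) {
  prim <- cnvs[is_primary_locus(cnvs, primary_region), , drop = FALSE]
  counts <- table(factor(prim$sample_id, levels = phenotypes$sample_id))
  missing <- names(counts)[counts == 0]
  if (length(missing))
    stop("sample(s) missing a primary-locus CNV: ",
         paste(missing, collapse = ", "))
  if (any(counts > 1))
    stop("sample(s) with multiple primary-locus CNVs: ",
         paste(names(counts)[counts > 1], collapse = ", "))
  prim$size <- cnv_size(prim)
  d <- merge(prim[, c("sample_id", "size")],
             phenotypes[, c("sample_id", "group")], by = "sample_id")
  by_group <- do.call(rbind, lapply(split(d$size, d$group), function(s)
    data.frame(n = length(s), mean_bp = mean(s),
               sd_bp = if (length(s) > 1) stats::sd(s) else 0)))
  by_group <- cbind(group = rownames(by_group), by_group)
  rownames(by_group) <- NULL
  cmp <- mann_whitney_u(d$size[d$group == "ASD"],
                        d$size[d$group == "non_ASD"])
  list(by_group = by_group, comparison = cmp)
}

#' Cohort descriptive statistics
#'
#' Group contrasts (Mann-Whitney) of age and the three clinical scores,
#' the Fisher exact parent-of-origin test, and the primary-CNV size
#' comparison.
#'
#' @param cnvs CNV data frame.
#' @param phenotypes phenotype data frame.
#' @param primary_region primary-locus region.
#' @return list with `score_comparisons` (data frame), `origin_table`,
#'   `origin_fisher_p`, and `dup7_sizes`.
#' @export
run_cohort_stats <- function(cnvs, phenotypes,
                             primary_region = .DUP7_REGION) {
  asd <- phenotypes$group == "ASD"
  rows <- lapply(c("age", "gca", "broadind", "css"), function(m) {
    v <- phenotypes[[m]]
    ok <- !is.na(v)
    cmp <- mann_whitney_u(v[asd & ok], v[!asd & ok])
    data.frame(measure = m, u = cmp$u, z = cmp$z,
               p_two_sided = cmp$p_two_sided, method = cmp$method,
               stringsAsFactors = FALSE)
  })
  tab <- parent_of_origin_table(phenotypes)
  fisher_p <- if (sum(tab) > 0) fisher_exact_2x2(tab) else NA_real_
  list(score_comparisons = do.call(rbind, rows),
       origin_table = tab,
       origin_fisher_p = fisher_p,
       dup7_sizes = summarize_dup7_sizes(cnvs, phenotypes, primary_region))
}
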