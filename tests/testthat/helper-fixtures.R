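# In-code fixtures and independent brute-force oracles shared by the tests.

FREQ_COLS <- c("freq_1kg", "freq_exac", "freq_gnomad")
PRED_COLS <- c("pred_cadd", "pred_sift", "pred_polyphen", "pred_provean",
               "pred_mutassessor", "pred_muttaster", "pred_phylop_mam",
               "pred_phylop_vert")
SPLICE_COLS <- c("spliceai_ag", "spliceai_al", "spliceai_dg", "spliceai_dl")

# one fully-populated variant row with overridable fields
variant_row <- function(sample_id = "S1", chrom = "chr1", pos = 100L,
                        ref = "A", alt = "T", zygosity = "het", gq = 99,
                        aaf = 0.5, effect = "missense", region = "exonic",
                        gene = "G1", freqs = c(NA, NA, NA),
                        preds = rep(NA_character_, 8),
                        spliceai = rep(NA_real_, 4), passed = TRUE) {
  d <- data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                  ref = ref, alt = alt, zygosity = zygosity, gq = gq,
                  aaf = aaf, effect = effect, region = region, gene = gene,
                  stringsAsFactors = FALSE)
  d[FREQ_COLS] <- as.list(as.numeric(freqs))
  d[PRED_COLS] <- as.list(as.character(preds))
  d[SPLICE_COLS] <- as.list(as.numeric(spliceai))
  d$passed_caller_filters <- passed
  d
}

variant_table <- function(...) do.call(rbind, list(...))

pheno_row <- function(sample_id = "S1", group = "non_ASD", sex = "F",
                      age = 10, gca = 80, broadind = 80, css = 2,
                      parent_of_origin = "maternal") {
  data.frame(sample_id = sample_id, group = group, sex = sex, age = age,
             gca = gca, broadind = broadind, css = css,
             parent_of_origin = parent_of_origin, stringsAsFactors = FALSE)
}

cnv_row <- function(sample_id = "S1", chrom = "chr1", start = 1000L,
                    end = 2000L, cnv_type = "DEL", genes = "",
                    is_rare = TRUE, category = "VUS") {
  data.frame(sample_id = sample_id, chrom = chrom, start = start,
             end = end, cnv_type = cnv_type, genes = genes,
             is_rare = is_rare, category = category, stringsAsFactors = FALSE)
}

# Benjamini-Hochberg by direct evaluation of q_(i) = min_{j>=i} m p_(j)/j
bh_oracle <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[i] <- min(1, min(m * ps[js] / js))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# two-sided Fisher p by hypergeometric enumeration (probability-mass rule)
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(a_range, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided Mann-Whitney p by full enumeration of group assignments,
# with U computed by direct pair counting (independent of the package's
# rank-sum formula)
mwu_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_pairs <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  mu <- na * length(b) / 2
  u_obs <- u_pairs(a, b)
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(idx)
    u_pairs(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# a small deterministic cohort for filter/burden unit tests
tiny_cohort <- function() {
  phen <- rbind(pheno_row("S1"), pheno_row("S2", group = "ASD", sex = "M"))
  variants <- variant_table(
    # S1: two rare LoF
    variant_row("S1", effect = "nonsense", gene = "GA",
                freqs = c(0.001, NA, 0.002)),
    variant_row("S1", effect = "frameshift_indel", gene = "GB",
                freqs = c(NA, NA, NA)),
    # S1: one rare likely-damaging missense (5 votes)
    variant_row("S1", effect = "missense", gene = "GC",
                freqs = c(0.005, NA, NA),
                preds = c(rep("damaging", 5), rep("benign", 3))),
    # S1: one common nonsense
    variant_row("S1", effect = "nonsense", gene = "GA",
                freqs = c(0.2, 0.15, 0.22)),
    # S2: one low-frequency-only LoF
    variant_row("S2", effect = "nonsense", gene = "GB",
                freqs = c(0.03, NA, NA)),
    # S2: one rare synonymous
    variant_row("S2", effect = "synonymous", gene = "GC",
                freqs = c(0.001, NA, NA)))
  cnvs <- rbind(
    cnv_row("S1", "chr7", 72700000L, 74200000L, "DUP",
            category = "pathogenic"),
    cnv_row("S2", "chr7", 72690000L, 74150000L, "DUP",
            category = "pathogenic"),
    cnv_row("S1", "chr2", 5000L, 9000L, "DEL", genes = "GD"),
    cnv_row("S2", "chr3", 100L, 200L, "DUP", genes = "GE,GC",
            is_rare = FALSE))
  list(variants = variants, cnvs = cnvs, phenotypes = phen)
}
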