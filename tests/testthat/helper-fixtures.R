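# Small fixtures shared across test files; everything is built in code.

# Uniform fragment map: n fragments of width w on one chromosome.
toy_fragment_map <- function(n = 20, w = 1000, chrom = "chr1") {
  fragment_map(rep(chrom, n), (seq_len(n) - 1) * w, seq_len(n) * w)
}

# Interaction set from bait/other-end fragment indices of a fragment map.
toy_interactions <- function(fm, bait_idx, oe_idx, scores,
                             bait_names = NULL) {
  mids <- (fm$start + fm$end) / 2
  pairs <- data.frame(
    bait_chr = fm$chrom[bait_idx], bait_start = fm$start[bait_idx],
    bait_end = fm$end[bait_idx], bait_id = fm$frag_id[bait_idx],
    bait_name = bait_names %||% paste0("B", bait_idx),
    oe_chr = fm$chrom[oe_idx], oe_start = fm$start[oe_idx],
    oe_end = fm$end[oe_idx], oe_id = fm$frag_id[oe_idx], oe_name = ".",
    dist = ifelse(fm$chrom[oe_idx] == fm$chrom[bait_idx],
                  mids[oe_idx] - mids[bait_idx], NA_real_),
    stringsAsFactors = FALSE
  )
  interaction_set(pairs, scores)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force specificity score: literal evaluation of the weighted-mean
# formula, independent of the package implementation.
brute_specificity <- function(x, W) {
  n <- length(x)
  vapply(seq_len(n), function(c) {
    num <- 0; den <- 0
    for (i in seq_len(n)) {
      if (i == c) next
      num <- num + W[c, i] * (x[c] - x[i])
      den <- den + W[c, i]
    }
    num / den
  }, numeric(1))
}

# Brute-force COGS: enumerate SNPs per block and multiply survival
# probabilities, independent of cogs_score().
brute_cogs <- function(posteriors, component_snps) {
  surv <- 1
  for (b in unique(posteriors$block)) {
    pb <- posteriors[posteriors$block == b, ]
    mass <- 0
    for (k in seq_len(nrow(pb))) {
      if (pb$snp_id[k] %in% component_snps) mass <- mass + pb$ppi[k]
    }
    surv <- surv * (1 - mass)
  }
  1 - surv
}

# A tiny regulatory-state table over given cell types.
toy_reg_states <- function(chrom, start, end, feature_class, activity) {
  df <- data.frame(
    chrom = chrom, start = start, end = end,
    name = paste0("F", seq_along(chrom)), score = 0, strand = ".",
    feature_class = feature_class, stringsAsFactors = FALSE
  )
  df <- cbind(df, activity)
  attr(df, "cell_types") <- colnames(activity)
  class(df) <- c("regulatory_states", "data.frame")
  df
}
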