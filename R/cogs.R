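#' Fine-mapping configuration
#'
#' Parameters of the approximate-Bayes-factor synthesis used for
#' single-causal-variant fine mapping: the prior variance `W` of the causal
#' effect (default `0.2^2 = 0.04`), and optionally the case proportion `s`
#' for case-control traits, which enters the per-SNP effect variance
#' `V = 1 / (2 n f (1 - f) s (1 - s))` (quantitative traits omit the
#' `s(1-s)` factor).
#'
#' @param W prior effect variance (> 0).
#' @param cc_ratio case proportion, or `NA` for quantitative traits.
#' @param include_null include a null (no-association) model in the
#'   posterior normalization (off by default; posteriors then sum to 1 over
#'   the block's SNPs).
#' @return list of class `finemap_config`.
#' @export
finemap_config <- function(W = 0.04, cc_ratio = NA_real_, include_null = FALSE) {
  if (W <= 0) stop_format("prior effect variance W must be positive")
  structure(list(W = W, cc_ratio = cc_ratio, include_null = include_null),
            class = "finemap_config")
}

#' Causal posteriors from approximate Bayes factors
#'
#' For each SNP, `z` is recovered from the two-sided p-value, the effect
#' variance is `V = 1/(2 n f (1-f))` (times `1/(s(1-s))` for case-control
#' traits with case proportion `s`), and the approximate Bayes factor is
#' `sqrt(V/(V+W)) * exp(z^2 W / (2 (V+W)))`. Posterior probabilities of
#' causality assume at most one causal variant per recombination block:
#' `ppi_i = ABF_i / sum_j ABF_j` (computed in log space for stability).
#' Only |z| is identifiable from a p-value; the ABF depends on z only
#' through its square.
#'
#' @param gwas a `gwas_table` for one or more blocks, with columns `p`,
#'   `maf`, `n` and `block` (single-block input may omit `block`).
#' @param cfg a [finemap_config()].
#' @return data.frame of class `posterior_set`: per-SNP `ppi` within each
#'   block (summing to 1 per block unless `include_null`).
#' @export
wakefield_posteriors <- function(gwas, cfg = finemap_config()) {
  if (any(gwas$maf <= 0, na.rm = TRUE)) stop_format("zero or negative MAF")
  if (is.null(gwas$block)) gwas$block <- 1L
  p <- gwas$p
  n_clamped <- sum(p == 0, na.rm = TRUE)
  p[p == 0] <- .Machine$double.xmin
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  f <- gwas$maf
  V <- 1 / (2 * gwas$n * f * (1 - f))
  s <- cfg$cc_ratio
  if (!is.na(s)) V <- V / (s * (1 - s))
  log_abf <- 0.5 * log(V / (V + cfg$W)) + z^2 * cfg$W / (2 * (V + cfg$W))
  ppi <- numeric(length(z))
  for (b in unique(gwas$block)) {
    i <- which(gwas$block == b)
    la <- log_abf[i]
    denom_terms <- if (cfg$include_null) c(la, 0) else la
    m <- max(denom_terms)
    ppi[i] <- exp(la - m) / sum(exp(denom_terms - m))
  }
  out <- data.frame(
    block = gwas$block, snp_id = gwas$snp_id %||% seq_along(z),
    chrom = gwas$chrom, pos = gwas$pos, ppi = ppi, log_abf = log_abf,
    imputed = gwas$imputed %||% FALSE
  )
  if (n_clamped > 0L) attr(out, "n_p_clamped") <- n_clamped
  class(out) <- c("posterior_set", "data.frame")
  out
}

#' @export
print.posterior_set <- function(x, ...) {
  cat(sprintf("Posterior set: %d SNPs in %d recombination block(s)\n",
              nrow(x), length(unique(x$block))))
  invisible(x)
}

#' SNP component sets of a gene
#'
#' Partitions SNPs relevant to a gene into three pairwise-disjoint sets,
#' with precedence coding > promoter > PIR:
#' 1. coding SNPs of the gene (from the consequence annotation);
#' 2. promoter SNPs: within the bait fragment(s) or one flanking fragment
#'    on each side, excluding coding SNPs;
#' 3. PIR SNPs: within other-end fragments having a high-confidence
#'    interaction with the gene's bait in at least one tissue of the tissue
#'    set, excluding coding and promoter SNPs. Trans PIRs participate.
#'
#' @param gene gene id.
#' @param ints an [interaction_set()].
#' @param gene_models data.frame with `gene_id`, `bait_frag`.
#' @param tissue_set character vector of cell types (may be empty).
#' @param coding data.frame `snp_id`, `gene_id` (consequence annotation).
#' @param frag_map a [fragment_map()].
#' @param snps data.frame with `snp_id`, `chrom`, `pos`.
#' @param score_threshold high-confidence CHiCAGO threshold.
#' @return list with character vectors `coding`, `promoter`, `pir`.
#' @export
gene_components <- function(gene, ints, gene_models, tissue_set, coding,
                            frag_map, snps, score_threshold = 5) {
  gm <- gene_models[gene_models$gene_id == gene, , drop = FALSE]
  if (nrow(gm) == 0L) stop_format("unknown gene %s", gene)
  coding_set <- unique(coding$snp_id[coding$gene_id == gene])
  coding_set <- intersect(coding_set, snps$snp_id)

  snp_frag <- locate_fragment(frag_map, snps$chrom, snps$pos)
  bait_frags <- unlist(lapply(gm$bait_frag, function(b) {
    same <- frag_map$frag_id[norm_chrom(frag_map$chrom) ==
                               norm_chrom(frag_map$chrom[frag_map$frag_id == b])]
    intersect(c(b - 1L, b, b + 1L), same)
  }))
  promoter_set <- setdiff(snps$snp_id[!is.na(snp_frag) & snp_frag %in% bait_frags],
                          coding_set)

  pir_set <- character(0)
  if (length(tissue_set) > 0L) {
    cols <- match(tissue_set, ints$cell_types)
    if (anyNA(cols)) stop_format("unknown tissue(s) in tissue set")
    hc <- apply(ints$scores[, cols, drop = FALSE] >= score_threshold, 1, any)
    rows <- hc & ints$pairs$bait_id %in% gm$bait_frag
    pir_frags <- unique(ints$pairs$oe_id[rows])
    pir_set <- setdiff(snps$snp_id[!is.na(snp_frag) & snp_frag %in% pir_frags],
                       c(coding_set, promoter_set))
  }
  list(coding = coding_set, promoter = promoter_set, pir = pir_set)
}

#' COGS gene score
#'
#' For each recombination block, the block gene score is the sum of causal
#' posterior probabilities over the union of the gene's coding, promoter
#' and PIR SNP sets; assuming statistical independence between blocks these
#' combine as `genescore = 1 - prod(1 - genescore.block)`.
#'
#' @param gene gene id.
#' @param posteriors a `posterior_set`.
#' @param components output of [gene_components()] for this gene and tissue
#'   set.
#' @param tissue_set label recorded in the result.
#' @return list of class `cogs_result` with the overall `genescore`, the
#'   per-block scores and the per-block component sums.
#' @export
cogs_score <- function(gene, posteriors, components, tissue_set = "all") {
  all_snps <- unique(c(components$coding, components$promoter, components$pir))
  blocks <- sort(unique(posteriors$block))
  per_block <- do.call(rbind, lapply(blocks, function(b) {
    pb <- posteriors[posteriors$block == b, , drop = FALSE]
    s_of <- function(set) sum(pb$ppi[pb$snp_id %in% set])
    data.frame(
      block = b,
      coding = s_of(components$coding),
      promoter = s_of(components$promoter),
      pir = s_of(components$pir),
      genescore_block = s_of(all_snps)
    )
  }))
  per_block <- per_block[per_block$genescore_block > 0, , drop = FALSE]
  genescore <- 1 - prod(1 - per_block$genescore_block)
  structure(
    list(gene = gene, tissue_set = tissue_set, genescore = genescore,
         blocks = per_block),
    class = "cogs_result"
  )
}

#' @export
print.cogs_result <- function(x, ...) {
  cat(sprintf("COGS: gene %s, tissue set %s, genescore %.4f over %d contributing block(s)\n",
              x$gene, paste(x$tissue_set, collapse = "+"), x$genescore, nrow(x$blocks)))
  invisible(x)
}

#' COGS scores for a set of genes
#'
#' Convenience wrapper computing [gene_components()] and [cogs_score()] for
#' every gene.
#'
#' @inheritParams gene_components
#' @param posteriors a `posterior_set`.
#' @return data.frame with one row per gene: `gene_id`, `tissue_set`,
#'   `n_blocks`, component totals and `genescore`.
#' @export
cogs_all_genes <- function(ints, gene_models, tissue_set, coding, frag_map,
                           posteriors, score_threshold = 5) {
  snps <- data.frame(snp_id = posteriors$snp_id, chrom = posteriors$chrom,
                     pos = posteriors$pos, stringsAsFactors = FALSE)
  rows <- lapply(gene_models$gene_id, function(g) {
    comp <- gene_components(g, ints, gene_models, tissue_set, coding,
                            frag_map, snps, score_threshold)
    res <- cogs_score(g, posteriors, comp, tissue_set)
    data.frame(
      gene_id = g, tissue_set = paste(tissue_set, collapse = "+"),
      n_blocks = nrow(res$blocks),
      coding = sum(res$blocks$coding), promoter = sum(res$blocks$promoter),
      pir = sum(res$blocks$pir), genescore = res$genescore,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' TAD-based gene prioritization score
#'
#' Baseline score that replaces interaction information with TAD
#' colocation: per TAD and trait, the posterior mass of each recombination
#' block restricted to the TAD (excluding coding SNPs) gives block TAD
#' scores, combined as `TAD.score = 1 - prod(1 - TADscore_block)`. The TAD
#' score is assigned to every gene whose TSS lies inside the TAD, and each
#' gene keeps its maximum across the supplied cell-type TAD sets; genes
#' outside all TADs are reported with `NA`.
#'
#' @param tad_sets named list of `tad_set` data.frames (one per cell type).
#' @param posteriors a `posterior_set`.
#' @param coding coding annotation (`snp_id`; any gene).
#' @param gene_models data.frame with `gene_id`, `chrom`, `tss`.
#' @return data.frame: `gene_id`, `tad_score` (max over cell types).
#' @export
tad_score <- function(tad_sets, posteriors, coding, gene_models) {
  pp <- posteriors[!posteriors$snp_id %in% coding$snp_id, , drop = FALSE]
  per_ct <- lapply(tad_sets, function(tads) {
    score_of_tad <- vapply(seq_len(nrow(tads)), function(t) {
      inside <- norm_chrom(pp$chrom) == norm_chrom(tads$chrom[t]) &
        pp$pos >= tads$start[t] & pp$pos < tads$end[t]
      if (!any(inside)) return(0)
      bs <- tapply(pp$ppi[inside], pp$block[inside], sum)
      1 - prod(1 - pmin(bs, 1))
    }, numeric(1))
    vapply(seq_len(nrow(gene_models)), function(g) {
      t <- which(norm_chrom(tads$chrom) == norm_chrom(gene_models$chrom[g]) &
                   gene_models$tss[g] >= tads$start & gene_models$tss[g] < tads$end)
      if (length(t) == 0L) NA_real_ else max(score_of_tad[t])
    }, numeric(1))
  })
  mat <- do.call(cbind, per_ct)
  best <- apply(mat, 1, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  data.frame(gene_id = gene_models$gene_id, tad_score = best,
             stringsAsFactors = FALSE)
}

#' Rank genes by COGS score
#'
#' Keeps genes whose overall score exceeds the threshold (default 0.5) and
#' ranks them by decreasing score, breaking ties by gene id.
#'
#' @param cogs data.frame with `gene_id` and `genescore` (as from
#'   [cogs_all_genes()]).
#' @param threshold minimum gene-level score (exclusive).
#' @return the filtered, ranked data.frame.
#' @export
prioritize <- function(cogs, threshold = 0.5) {
  keep <- cogs[!is.na(cogs$genescore) & cogs$genescore > threshold, , drop = FALSE]
  keep[order(-keep$genescore, keep$gene_id), , drop = FALSE]
}
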