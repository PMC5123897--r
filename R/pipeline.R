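#' Pipeline configuration
#'
#' Collects the thresholds and seeds of a full run with their standard
#' defaults: CHiCAGO high-confidence score 5, LD thresholds 0.6 (imputation
#' and QC support) and 0.8 (eQTL proxies), 10% FDR, gene-score cut-off 0.5,
#' asinh cap 4.3 and fine-mapping prior variance 0.04.
#'
#' @param seed master seed for every stochastic stage.
#' @param sim a [sim_config()] (defaults to `sim_config(seed)`).
#' @param score_threshold,r2_impute,r2_proxy,fdr,genescore_threshold,cap,W
#'   pipeline thresholds.
#' @param tissue_sets named list of cell-type sets scored by COGS and
#'   compared by blockshifter; the first set is the test set, the second
#'   the control set.
#' @param n_perm_blockshifter permutations for the blockshifter stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            sim = sim_config(seed),
                            score_threshold = 5,
                            r2_impute = 0.6,
                            r2_proxy = 0.8,
                            fdr = 0.1,
                            genescore_threshold = 0.5,
                            cap = 4.3,
                            W = 0.04,
                            tissue_sets = NULL,
                            n_perm_blockshifter = 1000) {
  if (missing(seed)) stop_format("pipeline_config requires an explicit seed")
  if (is.null(tissue_sets)) {
    tissue_sets <- sim$lineages[1:2]
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Orchestrates simulate -> fine-map -> score: generates the input bundle,
#' prepares GWAS summary statistics (QC filter, LD-proxy imputation),
#' computes per-block causal posteriors, COGS gene scores per tissue set,
#' the blockshifter comparison of the first two tissue sets, and gene
#' specificity scores. Outputs are written as TSVs together with a
#' machine-readable JSON manifest (seeds, thresholds, package version) that
#' suffices to reproduce the run.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the main result tables.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- simulate_inputs(config$sim, file.path(out_dir, "inputs"))
  sim <- inputs$interactome
  panel <- inputs$haplotypes$panel
  gwas <- inputs$gwas

  gwas <- qc_filter(gwas, panel)
  blocks <- partition_blocks(inputs$haplotypes$recomb_map)
  imputed <- pmi_impute(gwas, panel, blocks, r2_min = config$r2_impute)
  imputed$block <- assign_blocks(imputed$pos, blocks)
  post <- wakefield_posteriors(imputed, finemap_config(W = config$W))

  coding <- data.frame(snp_id = character(0), gene_id = character(0),
                       consequence = character(0))
  cogs <- do.call(rbind, lapply(names(config$tissue_sets), function(ts) {
    cogs_all_genes(sim$interactions, sim$gene_models, config$tissue_sets[[ts]],
                   coding, sim$fragment_map, post,
                   score_threshold = config$score_threshold)
  }))
  ranked <- prioritize(cogs, config$genescore_threshold)

  ts <- config$tissue_sets
  hc <- sim$interactions$scores >= config$score_threshold
  pir_frags_of <- function(set) {
    cols <- match(set, sim$interactions$cell_types)
    unique(sim$interactions$pairs$oe_id[apply(hc[, cols, drop = FALSE], 1, any)])
  }
  bs <- blockshifter_z(
    pir_frags_of(ts[[1]]), pir_frags_of(ts[[2]]), sim$fragment_map,
    data.frame(chrom = post$chrom, pos = post$pos, ppi = post$ppi),
    n_perm = config$n_perm_blockshifter, seed = derive_seed(config$seed, 21)
  )

  spec <- gene_specificity_matrix(sim$interactions, sim$reg_states,
                                  sim$gene_models,
                                  score_threshold = config$score_threshold,
                                  cap = config$cap)

  utils::write.table(imputed, file.path(out_dir, "gwas_imputed.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cogs, file.path(out_dir, "cogs_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ranked, file.path(out_dir, "cogs_prioritized.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(spec$s, file.path(out_dir, "gene_specificity.tsv"),
                     sep = "\t", quote = FALSE)
  bs_df <- data.frame(test_set = names(ts)[1], control_set = names(ts)[2],
                      delta = bs$delta, z = bs$z, n_perm = bs$n_perm)
  utils::write.table(bs_df, file.path(out_dir, "blockshifter.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "chicogs",
    version = as.character(utils::packageVersion("chicogs")),
    seed = config$seed,
    thresholds = config[c("score_threshold", "r2_impute", "r2_proxy", "fdr",
                          "genescore_threshold", "cap", "W")],
    sim = config$sim[setdiff(names(config$sim), c("cell_types", "lineages"))],
    tissue_sets = config$tissue_sets,
    outputs = c("gwas_imputed.tsv", "cogs_scores.tsv", "cogs_prioritized.tsv",
                "gene_specificity.tsv", "blockshifter.tsv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(gwas = imputed, posteriors = post, cogs = cogs,
                 prioritized = ranked, blockshifter = bs, specificity = spec,
                 inputs = inputs))
}

#' Planted-causal-variant recovery experiment
#'
#' Runs one replicate of the end-to-end recovery study: simulate an
#' interactome and haplotype panel, plant a causal variant (non-centrality
#' `ncp`) at a panel SNP inside a PIR belonging only to one target gene,
#' simulate GWAS summary statistics, transfer p-values to the panel
#' (PMI), fine-map each recombination block and compute COGS gene scores
#' for all genes. Used to quantify how often the planted gene ranks first.
#'
#' @param seed seed for this replicate.
#' @param ncp non-centrality at the causal SNP (default 6).
#' @param cfg a [sim_config()]; the default uses a 4 Mb region with 8
#'   captured genes.
#' @return list with `target` (gene id), `scores` (per-gene COGS table),
#'   `rank_first` (did the target strictly outscore all others) and the
#'   causal SNP id.
#' @export
cogs_recovery_experiment <- function(seed, ncp = 6,
                                     cfg = sim_config(seed = seed,
                                                      chrom_lengths = c(chr1 = 4e6),
                                                      n_genes = 8,
                                                      mean_interactions = 5)) {
  sim <- simulate_interactome(cfg)
  hp <- simulate_haplotype_panel(cfg)
  panel <- hp$panel
  ints <- sim$interactions
  hc <- apply(ints$scores >= 5, 1, any)
  pir_by_gene <- lapply(seq_len(nrow(sim$gene_models)), function(g) {
    rows <- which(hc & ints$pairs$bait_id == sim$gene_models$bait_frag[g] &
                    !is.na(ints$pairs$dist))
    unique(ints$pairs$oe_id[rows])
  })
  pir_use <- table(unlist(pir_by_gene))
  snp_frag <- locate_fragment(sim$fragment_map, panel$chrom, panel$legend$position)
  target <- NA_integer_; causal <- NA_integer_
  withr::with_seed(derive_seed(seed, 31), {
    for (g in sample(seq_along(pir_by_gene))) {
      uniq <- pir_by_gene[[g]][pir_use[as.character(pir_by_gene[[g]])] == 1]
      snps <- which(snp_frag %in% uniq)
      if (length(snps) > 0L) {
        target <- g
        causal <- snps[sample.int(length(snps), 1)]
        break
      }
    }
  })
  if (is.na(target)) stop_format("no gene has a private PIR containing a panel SNP")
  gwas <- simulate_gwas(panel, hp$recomb_map,
                        data.frame(snp_id = panel$legend$id[causal], ncp = ncp),
                        cfg)
  blocks <- partition_blocks(hp$recomb_map)
  imp <- pmi_impute(gwas, panel, blocks)
  imp$block <- assign_blocks(imp$pos, blocks)
  post <- wakefield_posteriors(imp)
  coding <- data.frame(snp_id = character(0), gene_id = character(0),
                       consequence = character(0))
  tab <- cogs_all_genes(ints, sim$gene_models, cfg$cell_types, coding,
                        sim$fragment_map, post)
  tg <- sim$gene_models$gene_id[target]
  list(
    target = tg, causal_snp = panel$legend$id[causal], scores = tab,
    rank_first = tab$genescore[tab$gene_id == tg] >
      max(tab$genescore[tab$gene_id != tg])
  )
}
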