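gwas_row <- function(pos, p, snp_id, chrom = "chr1", maf = 0.3, n = 10000) {
  data.frame(chrom = chrom, pos = pos, a1 = "A", a2 = "G", maf = maf, p = p,
             n = n, snp_id = snp_id, imputed = FALSE, stringsAsFactors = FALSE)
}

test_that("the spurious-association filter needs a supporting SNP", {
  panel <- haplotype_panel(
    data.frame(id = c("s1", "s2"), position = c(1e6, 5e6), a0 = "A", a1 = "G"),
    rbind(c(0, 1, 0, 1), c(1, 0, 1, 0))
  )
  # isolated genome-wide hit: nearest other SNP is far and weak
  g <- rbind(gwas_row(1e6, 1e-9, "s1"), gwas_row(5e6, 0.5, "s2"))
  expect_equal(qc_filter(g, panel)$snp_id, "s2")

  # a p < 1e-5 SNP 10 kb away rescues it
  g2 <- rbind(gwas_row(1e6, 1e-9, "s1"), gwas_row(1e6 + 1e4, 1e-6, "s2"))
  expect_equal(nrow(qc_filter(g2, panel)), 2)

  # LD arm: far away but r2 = 1 in the panel
  g3 <- rbind(gwas_row(1e6, 1e-9, "s1"), gwas_row(5e6, 1e-6, "s2"))
  expect_equal(nrow(qc_filter(g3, panel)), 2)

  # sub-threshold SNPs are never dropped
  g4 <- rbind(gwas_row(1e6, 1e-7, "s1"), gwas_row(5e6, 0.5, "s2"))
  expect_equal(nrow(qc_filter(g4, panel)), 2)
})

test_that("MHC-style region masking uses half-open bp bounds", {
  g <- rbind(gwas_row(30e6, 0.1, "a", chrom = "chr6"),
             gwas_row(24999999, 0.1, "b", chrom = "chr6"),
             gwas_row(30e6, 0.1, "c", chrom = "chr2"))
  out <- mask_region(g)
  expect_setequal(out$snp_id, c("b", "c"))
})

test_that("recombination blocks cut the map at 0.1-cM multiples", {
  # constant 1 cM/Mb over 1 Mb: ten 100-kb blocks
  rm1 <- data.frame(position = c(0, 1e6), rate = c(1, 0), map = c(0, 1))
  b <- partition_blocks(rm1)
  expect_equal(nrow(b), 10)
  expect_equal(b$start, seq(0, 9e5, by = 1e5))
  expect_equal(b$end - b$start, rep(1e5, 10))

  # total 0.35 cM: ceiling gives 4 blocks, the last one short
  rm2 <- data.frame(position = c(0, 7e5), rate = c(0.5, 0), map = c(0, 0.35))
  expect_equal(nrow(partition_blocks(rm2)), 4)

  # step equal to the whole map: a single block
  expect_equal(nrow(partition_blocks(rm2, step = 0.35)), 1)
})

test_that("LD-proxy p-value transfer copies, discards and flags", {
  # four panel SNPs; study has p for s1 and s3 only
  legend <- data.frame(id = paste0("s", 1:4), position = c(100, 200, 300, 400),
                       a0 = "A", a1 = "G")
  H <- rbind(
    c(0, 0, 1, 1, 0, 1),
    c(0, 0, 1, 1, 0, 1),   # s2: r2 = 1 with s1
    c(0, 1, 0, 1, 1, 0),
    c(1, 0, 0, 1, 1, 0)    # s4: weak LD with everything
  )
  panel <- haplotype_panel(legend, H)
  stopifnot(r_squared(panel, 3, 4) <= 0.6, r_squared(panel, 1, 4) <= 0.6)
  rm <- data.frame(position = c(0, 1000), rate = c(1, 0), map = c(0, 0.05))
  blocks <- partition_blocks(rm)
  gwas <- rbind(gwas_row(100, 3e-6, "s1"), gwas_row(300, 0.2, "s3"),
                gwas_row(900, 1e-4, "not_in_panel"))
  out <- pmi_impute(gwas, panel, blocks)
  # perfect-LD partner: p copied and flagged
  expect_equal(out$p[out$snp_id == "s2"], 3e-6)
  expect_true(out$imputed[out$snp_id == "s2"])
  expect_false(any(out$imputed[out$snp_id %in% c("s1", "s3")]))
  # r2max below threshold: discarded; study SNP outside panel: discarded
  expect_false("s4" %in% out$snp_id)
  expect_false("not_in_panel" %in% out$snp_id)
  expect_equal(attr(out, "log")$discarded_low_ld, 1L)
})

test_that("approximate Bayes factors and posteriors match the closed form", {
  # z = 3, V = 0.02, W = 0.04: ABF = sqrt(1/3) * exp(3)
  p3 <- 2 * pnorm(-3)
  n_for_V <- 1 / (2 * 0.02 * 0.3 * 0.7)  # makes V exactly 0.02 at maf 0.3
  g <- gwas_row(100, p3, "x", maf = 0.3, n = n_for_V)
  g$block <- 1
  post <- wakefield_posteriors(g, finemap_config(W = 0.04))
  expect_equal(exp(post$log_abf), sqrt(1 / 3) * exp(3), tolerance = 1e-9)
  expect_equal(round(exp(post$log_abf), 2), 11.6)

  # identical SNPs share the posterior equally; mass is conserved
  gk <- do.call(rbind, lapply(1:5, function(i) gwas_row(i * 100, 1e-4, paste0("s", i))))
  gk$block <- 1
  pk <- wakefield_posteriors(gk)
  expect_equal(pk$ppi, rep(0.2, 5))

  set.seed(19)
  gr <- do.call(rbind, lapply(1:60, function(i) {
    gwas_row(i * 100, runif(1), paste0("s", i), maf = runif(1, 0.05, 0.5))
  }))
  gr$block <- rep(1:12, each = 5)
  pr <- wakefield_posteriors(gr)
  sums <- tapply(pr$ppi, pr$block, sum)
  expect_equal(as.vector(sums), rep(1, 12), tolerance = 1e-12)

  # p = 0 is clamped, not an error; zero MAF is an error
  g0 <- gwas_row(100, 1, "z0"); g0$p <- 0
  expect_equal(wakefield_posteriors(g0)$ppi, 1)
  gneg <- gwas_row(100, 0.5, "zneg", maf = 0)
  expect_error(wakefield_posteriors(gneg), "MAF")
})

test_that("gene component sets are disjoint with coding precedence", {
  fm <- toy_fragment_map(6, 1000)
  scores <- matrix(c(9, 1), 1, 2, dimnames = list(NULL, c("Mon", "nCD4")))
  ints <- toy_interactions(fm, 3, 6, scores)
  gm <- data.frame(gene_id = "G1", bait_frag = 3, chrom = "chr1",
                   strand = "+", tss = 2500, coding = TRUE)
  snps <- data.frame(
    snp_id = paste0("v", 1:6), chrom = "chr1",
    pos = c(1500, 2500, 3500, 5500, 5600, 700)
  )
  coding <- data.frame(snp_id = c("v2", "v4"), gene_id = "G1",
                       consequence = "missense_variant")
  comp <- gene_components("G1", ints, gm, tissue_set = "Mon", coding, fm, snps)
  # hand assignment over the 6-fragment toy:
  #   v2 coding (in bait), v4 coding (in PIR) -> coding only
  #   v1 (frag 2), v3 (frag 4) flank the bait -> promoter
  #   v5 (frag 6) -> PIR; v6 (frag 1) -> nothing
  expect_setequal(comp$coding, c("v2", "v4"))
  expect_setequal(comp$promoter, c("v1", "v3"))
  expect_setequal(comp$pir, "v5")

  # empty tissue set: no PIR component
  comp0 <- gene_components("G1", ints, gm, tissue_set = character(0), coding, fm, snps)
  expect_equal(comp0$pir, character(0))

  # the tissue set matters: nCD4 alone has no high-confidence interaction
  comp_n <- gene_components("G1", ints, gm, tissue_set = "nCD4", coding, fm, snps)
  expect_equal(comp_n$pir, character(0))
})

test_that("COGS combines block scores by independence", {
  post <- structure(data.frame(
    block = c(1, 1, 2, 2), snp_id = c("a", "b", "c", "d"),
    chrom = "chr1", pos = c(100, 200, 300, 400),
    ppi = c(0.5, 0.5, 0.5, 0.5), log_abf = 0, imputed = FALSE
  ), class = c("posterior_set", "data.frame"))
  comp <- list(coding = character(0), promoter = character(0), pir = c("a", "c"))
  res <- cogs_score("G1", post, comp)
  expect_equal(res$genescore, 0.75)  # 1 - 0.5 * 0.5

  # single block equals the block score
  res1 <- cogs_score("G1", post[post$block == 1, ], comp)
  expect_equal(res1$genescore, 0.5)

  # covering every SNP of a block saturates it
  full <- cogs_score("G1", post[post$block == 1, ],
                     list(coding = "a", promoter = "b", pir = character(0)))
  expect_equal(full$genescore, 1)
})

test_that("COGS equals brute-force survival enumeration on random toys", {
  set.seed(20)
  for (rep in 1:8) {
    n_blocks <- sample(1:3, 1)
    snps <- paste0("t", 1:20)
    blk <- sort(sample(n_blocks, 20, replace = TRUE))
    ppi_raw <- runif(20)
    ppi <- unsplit(lapply(split(ppi_raw, blk), function(v) v / sum(v)), blk)
    post <- structure(data.frame(
      block = blk, snp_id = snps, chrom = "chr1", pos = 1:20 * 100,
      ppi = ppi, log_abf = 0, imputed = FALSE
    ), class = c("posterior_set", "data.frame"))
    sets <- split(sample(snps, 12), rep(1:3, each = 4))
    comp <- list(coding = sets[[1]], promoter = sets[[2]], pir = sets[[3]])
    res <- cogs_score("G", post, comp)
    expect_equal(res$genescore, brute_cogs(post, unlist(comp)), tolerance = 1e-12)
  }
})

test_that("COGS genescore is monotone in the tissue set", {
  cfg <- sim_config(seed = 111, chrom_lengths = c(chr1 = 2e6), n_genes = 8)
  sim <- simulate_interactome(cfg)
  hp <- simulate_haplotype_panel(cfg)
  gwas <- simulate_gwas(hp$panel, hp$recomb_map, NULL, cfg)
  blocks <- partition_blocks(hp$recomb_map)
  gwas$block <- assign_blocks(gwas$pos, blocks)
  post <- wakefield_posteriors(gwas)
  coding <- data.frame(snp_id = character(0), gene_id = character(0),
                       consequence = character(0))
  small <- cogs_all_genes(sim$interactions, sim$gene_models, "Mon", coding,
                          sim$fragment_map, post)
  big <- cogs_all_genes(sim$interactions, sim$gene_models, c("Mon", "nCD4", "Ery"),
                        coding, sim$fragment_map, post)
  expect_true(all(big$genescore >= small$genescore - 1e-12))
})

test_that("TAD scores aggregate block mass inside domains", {
  post <- structure(data.frame(
    block = c(1, 1, 2, 2), snp_id = c("a", "b", "c", "d"), chrom = "chr1",
    pos = c(100, 2000, 1100, 3000), ppi = c(0.2, 0.8, 0.3, 0.7),
    log_abf = 0, imputed = FALSE
  ), class = c("posterior_set", "data.frame"))
  coding0 <- data.frame(snp_id = character(0), gene_id = character(0))
  gm <- data.frame(gene_id = c("Gin", "Gout"), chrom = "chr1", tss = c(150, 9000))

  # TAD covering SNPs worth 0.2 of block 1 and 0.3 of block 2
  tads <- structure(data.frame(chrom = "chr1", start = 0, end = 1150),
                    class = c("tad_set", "data.frame"))
  ts <- tad_score(list(ct1 = tads), post, coding0, gm)
  expect_equal(ts$tad_score[ts$gene_id == "Gin"], 1 - 0.8 * 0.7)
  expect_true(is.na(ts$tad_score[ts$gene_id == "Gout"]))

  # a TAD containing a full block (no coding SNPs) saturates
  tads2 <- structure(data.frame(chrom = "chr1", start = 0, end = 2500),
                     class = c("tad_set", "data.frame"))
  ts2 <- tad_score(list(ct1 = tads2), post, coding0, gm)
  expect_equal(ts2$tad_score[ts2$gene_id == "Gin"], 1)

  # coding SNPs are removed before summing
  coding1 <- data.frame(snp_id = "b", gene_id = "Gx")
  ts3 <- tad_score(list(ct1 = tads2), post, coding1, gm)
  expect_equal(ts3$tad_score[ts3$gene_id == "Gin"], 1 - 0.8 * 0.7)
})

test_that("prioritization thresholds and orders gene scores", {
  tab <- data.frame(gene_id = c("B", "A", "C", "D"),
                    genescore = c(0.51, 0.49, 0.9, 0.9))
  out <- prioritize(tab)
  expect_equal(out$gene_id, c("C", "D", "B"))  # ties broken by gene id
  expect_false("A" %in% out$gene_id)
  empty <- prioritize(tab[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("missing allele frequencies are computed from the panel", {
  panel <- haplotype_panel(
    data.frame(id = c("a", "b"), position = c(10, 20), a0 = "A", a1 = "G"),
    rbind(c(0, 1, 1, 1), c(0, 0, 1, 1))
  )
  g <- data.frame(chrom = "chr1", pos = c(10, 20), a1 = "A", a2 = "G",
                  maf = c(NA, 0.4), p = 0.5, snp_id = c("a", "b"),
                  imputed = FALSE)
  class(g) <- c("gwas_table", "data.frame")
  out <- add_panel_maf(g, panel)
  expect_equal(out$maf, c(0.25, 0.4))
})
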