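#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: a HindIII-like fragment tiling, a blood-cell panel with lineage
#' structure, lineage-specific and invariant interaction clusters, enhancer
#' activity coupled to interactions, haplotypes with block-wise LD decay,
#' GWAS z-scores under at most one causal variant per recombination block,
#' and lead eQTLs planted inside PIRs.
#'
#' @param seed master seed; mandatory. Every stochastic generator takes an
#'   explicit seed derived from it.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param mean_fragment_len expected restriction fragment length in bp
#'   (default 4096, the 4-cutter/6-cutter HindIII expectation).
#' @param cell_types cell-type labels of the panel.
#' @param lineages named list partitioning `cell_types` into lineages; each
#'   lineage induces one planted interaction cluster, plus an invariant
#'   cluster shared by all cell types.
#' @param n_genes number of captured (baited) genes.
#' @param mean_interactions mean number of interactions per gene.
#' @param n_haplotypes number of reference haplotypes (must be even).
#' @param n_snps number of panel SNPs.
#' @param n_founders founder haplotypes for the mosaic-copying process.
#' @param switch_rate haplotype mosaic switch intensity per cM; larger values
#'   give faster LD decay. The default of 30 per cM puts the mean r-squared
#'   half-distance at a few kb, the fast end of European-ancestry panels.
#' @param snp_density expected panel SNPs per bp used when `n_snps` is not
#'   given explicitly; the default of 1/3000 emulates a dense genotyping
#'   array rather than full sequencing density.
#' @param hotspots_per_mb recombination hotspots (about 2 kb wide) per Mb in
#'   the simulated genetic map; 0 (the default) gives a smooth map whose
#'   0.1-cM blocks all have comparable physical size.
#' @param ncp non-centrality (mean |z|) at a planted causal SNP.
#' @param n_gwas GWAS sample size attached to simulated summary statistics.
#' @param eqtl_fraction fraction of genes whose lead eQTL is planted inside a
#'   true PIR of that gene.
#' @param coupling enhancer-activity coupling strength in `[0, 1]`: 1 ties
#'   activity exactly to high-confidence interactions, 0 makes them
#'   independent.
#' @param enhancer_fraction fraction of other-end fragments carrying a distal
#'   enhancer feature.
#' @param p_active baseline probability that an uncoupled enhancer is active.
#' @param expr_effect additive expression increment per interacting active
#'   enhancer; `expr_sd` is the Gaussian noise sd.
#' @param expr_sd see `expr_effect`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       chrom_lengths = c(chr1 = 10e6),
                       mean_fragment_len = 4096,
                       cell_types = c("Mon", "Mac0", "Mac1", "Mac2", "Neu", "MK",
                                      "Ery", "EndP", "nCD4", "tCD4", "aCD4", "naCD4",
                                      "nCD8", "tCD8", "nB", "tB", "FoeT"),
                       lineages = list(
                         myeloid = c("Mon", "Mac0", "Mac1", "Mac2", "Neu", "MK", "Ery", "EndP"),
                         lymphoid = c("nCD4", "tCD4", "aCD4", "naCD4", "nCD8", "tCD8", "nB", "tB", "FoeT")
                       ),
                       n_genes = 40,
                       mean_interactions = 6,
                       n_haplotypes = 100,
                       snp_density = 1 / 3000,
                       n_snps = round(chrom_lengths[[1]] * snp_density),
                       n_founders = 8,
                       switch_rate = 30,
                       hotspots_per_mb = 0,
                       ncp = 6,
                       n_gwas = 10000,
                       eqtl_fraction = 0.5,
                       coupling = 0.8,
                       enhancer_fraction = 0.9,
                       p_active = 0.3,
                       expr_effect = 1.5,
                       expr_sd = 1) {
  if (missing(seed)) stop_format("sim_config requires an explicit seed")
  if (coupling < 0 || coupling > 1) stop_format("coupling strength must lie in [0, 1]")
  if (n_haplotypes %% 2 != 0) stop_format("n_haplotypes must be even")
  counts <- c(chrom_lengths, mean_fragment_len, n_genes, n_haplotypes, n_snps,
              n_founders, n_gwas, mean_interactions)
  if (any(counts <= 0)) stop_format("all sizes in sim_config must be positive")
  if (!setequal(unlist(lineages), cell_types)) {
    stop_format("lineages must partition cell_types")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a restriction fragment map
#'
#' Cut sites are placed by exponential spacing with the configured mean
#' fragment length, emulating a genome-wide restriction digest; fragments
#' tile each chromosome.
#'
#' @param cfg a [sim_config()].
#' @param seed seed (defaults to the config master seed).
#' @return a [fragment_map()].
#' @export
simulate_fragment_map <- function(cfg, seed = cfg$seed) {
  withr::with_seed(seed, {
    chroms <- character(0); starts <- numeric(0); ends <- numeric(0)
    for (ch in names(cfg$chrom_lengths)) {
      L <- cfg$chrom_lengths[[ch]]
      n_exp <- ceiling(L / cfg$mean_fragment_len * 1.5) + 10
      cuts <- cumsum(stats::rexp(n_exp, rate = 1 / cfg$mean_fragment_len))
      while (max(cuts) < L) {
        cuts <- c(cuts, max(cuts) + cumsum(stats::rexp(n_exp, 1 / cfg$mean_fragment_len)))
      }
      cuts <- floor(cuts[cuts < L])
      cuts <- unique(cuts[cuts > 0])
      bounds <- c(0, cuts, L)
      chroms <- c(chroms, rep(ch, length(bounds) - 1L))
      starts <- c(starts, bounds[-length(bounds)])
      ends <- c(ends, bounds[-1L])
    }
    fragment_map(chroms, starts, ends)
  })
}

#' Simulate a PCHi-C interactome with planted structure
#'
#' Baits are assigned to genes; each interaction is drawn from a planted
#' cluster (one per lineage, plus a cell-type-invariant cluster) with high
#' CHiCAGO scores (>= 5) in member cell types and low scores elsewhere. A
#' configurable fraction of other ends carries a distal-enhancer feature
#' whose per-cell-type activity co-occurs with high scores at the configured
#' coupling strength; gene expression is generated additively in the number
#' of interacting active enhancers plus Gaussian noise. The planted truth
#' (cluster labels) is returned for recovery tests.
#'
#' @param cfg a [sim_config()].
#' @param frag_map a [fragment_map()]; simulated from `cfg` if missing.
#' @param seed seed.
#' @return list with elements `interactions` ([interaction_set()]),
#'   `reg_states`, `expression` (genes x cell types), `gene_models`,
#'   `fragment_map` (baits flagged) and `truth`.
#' @export
simulate_interactome <- function(cfg, frag_map = NULL, seed = cfg$seed) {
  if (is.null(frag_map)) frag_map <- simulate_fragment_map(cfg, seed = derive_seed(seed, 1))
  withr::with_seed(derive_seed(seed, 2), {
    ct <- cfg$cell_types
    clusters <- c(cfg$lineages, list(invariant = ct))
    mids <- fragment_mid(frag_map)

    # baits: interior fragments, one gene per bait
    interior <- which(with(frag_map, {
      lens <- stats::ave(end, chrom, FUN = max)
      mids > 0.05 * lens & mids < 0.95 * lens
    }))
    bait_idx <- sort(sample(interior, cfg$n_genes))
    frag_map$is_bait[bait_idx] <- TRUE
    gene_models <- data.frame(
      gene_id = sprintf("G%03d", seq_len(cfg$n_genes)),
      chrom = frag_map$chrom[bait_idx],
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
      tss = round(mids[bait_idx]),
      bait_frag = frag_map$frag_id[bait_idx],
      coding = TRUE,
      stringsAsFactors = FALSE
    )

    rows <- list(); labels <- character(0)
    for (g in seq_len(cfg$n_genes)) {
      n_i <- 1L + stats::rpois(1, cfg$mean_interactions - 1)
      b <- bait_idx[g]
      # draw distances in a batch and keep the first n_i distinct other ends
      d <- stats::rlnorm(4 * n_i + 40, meanlog = log(3e5), sdlog = 0.9) *
        sample(c(-1, 1), 4 * n_i + 40, replace = TRUE)
      cand <- locate_fragment(frag_map, rep(frag_map$chrom[b], length(d)),
                              round(mids[b] + d))
      cand <- unique(cand[!is.na(cand) & cand != frag_map$frag_id[b]])
      oes <- utils::head(cand, n_i)
      for (oe in oes) {
        rows[[length(rows) + 1L]] <- c(g, b, oe)
        labels <- c(labels, sample(names(clusters), 1))
      }
    }
    m <- do.call(rbind, rows)
    gi <- m[, 1]; bi <- m[, 2]; oi <- m[, 3]

    # CHiCAGO scores: high in cluster member cell types, low elsewhere
    scores <- matrix(stats::runif(nrow(m) * length(ct), 0, 3),
                     nrow = nrow(m), dimnames = list(NULL, ct))
    for (r in seq_len(nrow(m))) {
      members <- clusters[[labels[r]]]
      scores[r, members] <- 5 + stats::rexp(length(members), rate = 1 / 4)
    }

    pairs <- data.frame(
      bait_chr = frag_map$chrom[bi], bait_start = frag_map$start[bi],
      bait_end = frag_map$end[bi], bait_id = frag_map$frag_id[bi],
      bait_name = gene_models$gene_id[gi],
      oe_chr = frag_map$chrom[oi], oe_start = frag_map$start[oi],
      oe_end = frag_map$end[oi], oe_id = frag_map$frag_id[oi], oe_name = ".",
      dist = mids[oi] - mids[bi], stringsAsFactors = FALSE
    )
    ints <- interaction_set(pairs, scores)

    # regulatory features: distal enhancers on other ends, promoters on baits
    oe_unique <- sort(unique(oi))
    has_enh <- stats::runif(length(oe_unique)) < cfg$enhancer_fraction
    enh_frag <- oe_unique[has_enh]
    hi_by_frag <- matrix(FALSE, length(enh_frag), length(ct), dimnames = list(NULL, ct))
    for (k in seq_along(enh_frag)) {
      r <- which(oi == enh_frag[k])
      hi_by_frag[k, ] <- apply(scores[r, , drop = FALSE] >= 5, 2, any)
    }
    coupled <- matrix(stats::runif(length(enh_frag) * length(ct)) < cfg$coupling,
                      length(enh_frag), length(ct))
    base_active <- matrix(stats::runif(length(enh_frag) * length(ct)) < cfg$p_active,
                          length(enh_frag), length(ct))
    active <- ifelse(coupled, hi_by_frag, base_active)
    other_states <- c("poised", "repressed", "inactive")
    enh_state <- matrix(
      ifelse(active, "active",
             sample(other_states, length(active), replace = TRUE)),
      nrow = length(enh_frag), dimnames = list(NULL, ct)
    )
    pad <- pmax(floor((frag_map$end[enh_frag] - frag_map$start[enh_frag]) * 0.25), 1)
    enh_df <- data.frame(
      chrom = frag_map$chrom[enh_frag],
      start = frag_map$start[enh_frag] + pad,
      end = frag_map$end[enh_frag] - pad,
      name = sprintf("ENH%04d", seq_along(enh_frag)),
      score = 0, strand = ".",
      feature_class = "distal_enhancer", stringsAsFactors = FALSE
    )
    enh_df <- cbind(enh_df, as.data.frame(enh_state, stringsAsFactors = FALSE))

    prom_state <- matrix(
      ifelse(stats::runif(length(bait_idx) * length(ct)) < 0.9, "active",
             sample(other_states, length(bait_idx) * length(ct), replace = TRUE)),
      nrow = length(bait_idx), dimnames = list(NULL, ct)
    )
    prom_df <- data.frame(
      chrom = frag_map$chrom[bait_idx],
      start = pmax(gene_models$tss - 500, frag_map$start[bait_idx]),
      end = pmin(gene_models$tss + 500, frag_map$end[bait_idx]),
      name = sprintf("PROM%04d", seq_along(bait_idx)),
      score = 0, strand = gene_models$strand,
      feature_class = "promoter", stringsAsFactors = FALSE
    )
    prom_df <- cbind(prom_df, as.data.frame(prom_state, stringsAsFactors = FALSE))
    reg <- rbind(prom_df, enh_df)
    attr(reg, "cell_types") <- ct
    class(reg) <- c("regulatory_states", "data.frame")

    # expression: additive in the number of interacting active enhancers
    expr <- matrix(0, cfg$n_genes, length(ct),
                   dimnames = list(gene_models$gene_id, ct))
    enh_active_lookup <- function(frag, c_idx) {
      k <- match(frag, enh_frag)
      !is.na(k) & enh_state[cbind(k, c_idx)] == "active"
    }
    for (ci in seq_along(ct)) {
      n_act <- vapply(seq_len(cfg$n_genes), function(g) {
        r <- which(gi == g & scores[, ci] >= 5)
        sum(enh_active_lookup(oi[r], ci))
      }, numeric(1))
      expr[, ci] <- 2 + cfg$expr_effect * n_act +
        stats::rnorm(cfg$n_genes, sd = cfg$expr_sd)
    }

    list(
      interactions = ints, reg_states = reg, expression = expr,
      gene_models = gene_models, fragment_map = frag_map,
      truth = list(cluster = labels, clusters = clusters,
                   enhancer_frag = enh_frag, enhancer_active = enh_state)
    )
  })
}

#' Simulate a reference haplotype panel with LD decay
#'
#' Haplotypes are built by mosaic copying: founders are drawn from per-SNP
#' allele frequencies, and each further haplotype copies a random existing
#' one, switching template with probability proportional to the local
#' genetic distance. This yields r-squared decaying with genetic distance
#' without claiming any population-genetic model. A recombination map with
#' heterogeneous local rates is emitted alongside.
#'
#' @param cfg a [sim_config()].
#' @param region_length panel region length in bp (defaults to the first
#'   chromosome length).
#' @param seed seed.
#' @return list with `panel` ([haplotype_panel()]) and `recomb_map`.
#' @export
simulate_haplotype_panel <- function(cfg, region_length = cfg$chrom_lengths[[1]],
                                     seed = cfg$seed) {
  withr::with_seed(derive_seed(seed, 3), {
    chrom <- names(cfg$chrom_lengths)[1]
    pos <- sort(sample.int(region_length - 1L, cfg$n_snps))

    # piecewise-constant background rate plus narrow (~2 kb) hotspots, the
    # characteristic width of human recombination hotspots
    n_seg <- 30L
    seg_bounds <- round(seq(0, region_length, length.out = n_seg + 1L))
    rate <- stats::rgamma(n_seg, shape = 3, rate = 3)        # cM/Mb, mean 1
    seg_cm <- rate * diff(seg_bounds) / 1e6
    bg_at <- function(p) {
      k <- pmax(pmin(findInterval(p, seg_bounds, rightmost.closed = TRUE), n_seg), 1L)
      c(0, cumsum(seg_cm))[k] + rate[k] * (p - seg_bounds[k]) / 1e6
    }
    n_hot <- round(region_length / 1e6 * (cfg$hotspots_per_mb %||% 0))
    hot_width <- 2000
    hot_pos <- if (n_hot > 0L) sort(stats::runif(n_hot, 0, region_length - hot_width)) else numeric(0)
    hot_cm <- stats::runif(n_hot, 0.05, 0.3)
    map_at <- function(p) {
      extra <- if (n_hot == 0L) 0 else vapply(p, function(x) {
        sum(hot_cm * pmin(pmax((x - hot_pos) / hot_width, 0), 1))
      }, numeric(1))
      bg_at(p) + extra
    }
    grid <- sort(unique(c(seg_bounds, round(hot_pos), round(hot_pos + hot_width))))
    recomb_map <- data.frame(
      position = grid,
      rate = c(diff(map_at(grid)) / pmax(diff(grid), 1) * 1e6, 0),
      map = map_at(grid)
    )

    cm <- map_at(pos)
    d_cm <- diff(cm)
    p_freq <- stats::runif(cfg$n_snps, 0.1, 0.9)
    H <- matrix(0L, cfg$n_snps, cfg$n_haplotypes)
    for (f in seq_len(cfg$n_founders)) {
      H[, f] <- stats::rbinom(cfg$n_snps, 1, p_freq)
    }
    switch_p <- 1 - exp(-cfg$switch_rate * d_cm)
    for (h in (cfg$n_founders + 1L):cfg$n_haplotypes) {
      sw <- which(stats::runif(cfg$n_snps - 1L) < switch_p)
      seg_start <- c(1L, sw + 1L)
      seg_end <- c(sw, cfg$n_snps)
      tmpl <- sample.int(h - 1L, length(seg_start), replace = TRUE)
      out <- integer(cfg$n_snps)
      for (k in seq_along(seg_start)) {
        out[seg_start[k]:seg_end[k]] <- H[seg_start[k]:seg_end[k], tmpl[k]]
      }
      H[, h] <- out
    }
    poly <- rowMeans(H) > 0 & rowMeans(H) < 1
    H <- H[poly, , drop = FALSE]
    pos <- pos[poly]
    legend <- data.frame(
      id = sprintf("rs%05d", seq_len(sum(poly))),
      position = pos, a0 = "A", a1 = "G", stringsAsFactors = FALSE
    )
    list(panel = haplotype_panel(legend, H, chrom = chrom), recomb_map = recomb_map)
  })
}

#' Simulate GWAS summary statistics under a single causal variant per block
#'
#' Within each recombination block, the z-score vector is drawn from a
#' multivariate normal with mean `Sigma %*% lambda` and covariance `Sigma`,
#' the LD correlation matrix of the block in the panel; `lambda` is non-zero
#' only at a planted causal SNP (magnitude `ncp`). Unplanted blocks have
#' `lambda = 0`. Two-sided p-values are attached.
#'
#' @param panel a [haplotype_panel()].
#' @param recomb_map recombination map as from [simulate_haplotype_panel()].
#' @param planted data.frame with columns `snp_id` and `ncp`; may be empty.
#' @param cfg a [sim_config()] (supplies `n_gwas`).
#' @param seed seed.
#' @param ridge diagonal regularization added to a (near-)singular LD matrix.
#' @return a `gwas_table` with an extra `z` column and the block id.
#' @export
simulate_gwas <- function(panel, recomb_map, planted = NULL, cfg, seed = cfg$seed,
                          ridge = 1e-6) {
  blocks <- partition_blocks(recomb_map)
  withr::with_seed(derive_seed(seed, 4), {
    pos <- panel$legend$position
    blk <- assign_blocks(pos, blocks)
    lambda <- rep(0, length(pos))
    if (!is.null(planted) && nrow(planted) > 0L) {
      idx <- match(planted$snp_id, panel$legend$id)
      if (anyNA(idx)) stop_format("planted causal SNP not found in panel")
      lambda[idx] <- planted$ncp
    }
    z <- rep(NA_real_, length(pos))
    for (b in unique(blk)) {
      i <- which(blk == b)
      if (length(i) == 1L) {
        z[i] <- lambda[i] + stats::rnorm(1)
        next
      }
      R <- stats::cor(t(panel$H[i, , drop = FALSE]))
      eps <- ridge
      repeat {
        L <- tryCatch(chol(R + diag(eps, nrow(R))), error = function(e) NULL)
        if (!is.null(L)) break
        eps <- eps * 10
        if (eps > 1) stop_format("LD matrix could not be regularized")
      }
      Sigma <- R + diag(eps, nrow(R))
      z[i] <- as.vector(Sigma %*% lambda[i]) + as.vector(t(L) %*% stats::rnorm(length(i)))
    }
    maf <- panel_maf(panel)
    df <- data.frame(
      chrom = panel$chrom, pos = pos,
      a1 = panel$legend$a0, a2 = panel$legend$a1,
      maf = maf, p = 2 * stats::pnorm(-abs(z)),
      n = cfg$n_gwas, z = z, block = blk,
      snp_id = panel$legend$id,
      imputed = FALSE, stringsAsFactors = FALSE
    )
    class(df) <- c("gwas_table", "data.frame")
    df
  })
}

#' Plant lead eQTLs with respect to promoter-interacting regions
#'
#' For the requested fraction of genes the lead eQTL SNP is placed inside a
#' true PIR of that gene; the remaining genes receive lead eQTLs at
#' distance-matched positions outside their own PIRs. Genes for which no
#' panel SNP satisfies the requirement are skipped and reported.
#'
#' @param interactome output of [simulate_interactome()].
#' @param panel a [haplotype_panel()] providing SNP positions.
#' @param fraction fraction of genes with a PIR-resident lead eQTL.
#' @param seed seed.
#' @param score_threshold CHiCAGO score defining a PIR.
#' @param fdr_r2 LD threshold defining the lead's accompanying set of
#'   FDR-significant eQTL SNPs (real eQTL signals span many significant
#'   SNPs in LD with the lead; these are emitted as non-lead `fdr_pass`
#'   rows).
#' @return an `eqtl_table` (one lead row per gene plus its FDR-significant
#'   companions) with attribute `skipped`.
#' @export
plant_eqtls <- function(interactome, panel, fraction, seed, score_threshold = 5,
                        fdr_r2 = 0.5) {
  if (fraction < 0 || fraction > 1) stop_format("fraction must lie in [0, 1]")
  withr::with_seed(derive_seed(seed, 5), {
    ints <- interactome$interactions
    gm <- interactome$gene_models
    pos <- panel$legend$position
    hc <- apply(ints$scores >= score_threshold, 1, any)
    out <- list(); skipped <- character(0)
    in_pir <- sample(c(rep(TRUE, round(fraction * nrow(gm))),
                       rep(FALSE, nrow(gm) - round(fraction * nrow(gm)))))
    for (g in seq_len(nrow(gm))) {
      rows <- which(hc & ints$pairs$bait_id == gm$bait_frag[g] &
                      norm_chrom(ints$pairs$oe_chr) == norm_chrom(panel$chrom))
      if (length(rows) == 0L) { skipped <- c(skipped, gm$gene_id[g]); next }
      pir_start <- ints$pairs$oe_start[rows]; pir_end <- ints$pairs$oe_end[rows]
      inside <- which(vapply(pos, function(p) any(p >= pir_start & p < pir_end), logical(1)))
      snp <- NA_integer_
      if (in_pir[g]) {
        if (length(inside) > 0L) snp <- if (length(inside) == 1L) inside else sample(inside, 1)
      } else {
        # distance-matched placement drawn without regard to PIR status:
        # the distance comes from the pooled bait-to-PIR distance
        # distribution (not this gene's own PIRs, which would replant the
        # eQTL at a true PIR position), with a random side and uniform
        # jitter, so background genes overlap PIRs only at the chance rate
        d_pool <- abs(ints$pairs$dist[hc & !is.na(ints$pairs$dist)])
        d0 <- d_pool[sample.int(length(d_pool), 1)] * stats::runif(1, 0.5, 1.5)
        target <- gm$tss[g] + d0 * sample(c(-1, 1), 1)
        cand <- which(abs(pos - target) < 5e4)
        if (length(cand) == 0L) cand <- order(abs(pos - target))[1:3]
        snp <- cand[which.min(abs(pos[cand] - target))]
      }
      if (is.na(snp)) { skipped <- c(skipped, gm$gene_id[g]); next }
      lead_id <- panel$legend$id[snp]
      companions <- setdiff(ld_proxies(lead_id, panel, fdr_r2), lead_id)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gm$gene_id[g],
        snp_id = c(lead_id, companions),
        p = c(stats::runif(1, 1e-12, 1e-6),
              stats::runif(length(companions), 1e-6, 1e-3)),
        fdr_pass = TRUE,
        lead = c(TRUE, rep(FALSE, length(companions))),
        stringsAsFactors = FALSE
      )
    }
    df <- if (length(out) > 0L) do.call(rbind, out) else
      data.frame(gene_id = character(0), snp_id = character(0), p = numeric(0),
                 fdr_pass = logical(0), lead = logical(0))
    attr(df, "skipped") <- skipped
    class(df) <- c("eqtl_table", "data.frame")
    df
  })
}

#' Write the full synthetic input bundle to a directory
#'
#' Generates every input the pipeline consumes (peak matrix, regulatory
#' states, expression, GWAS summary statistics, haplotypes, recombination
#' map, eQTL table, coding annotation) and writes them in the package's text
#' formats.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
simulate_inputs <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_interactome(cfg)
  hp <- simulate_haplotype_panel(cfg)
  causal <- withr::with_seed(derive_seed(cfg$seed, 6), {
    data.frame(snp_id = sample(hp$panel$legend$id, 1), ncp = cfg$ncp)
  })
  gwas <- simulate_gwas(hp$panel, hp$recomb_map, causal, cfg)
  eqtls <- plant_eqtls(sim, hp$panel, cfg$eqtl_fraction, seed = cfg$seed)
  coding <- data.frame(snp_id = character(0), gene_id = character(0),
                       consequence = character(0))
  write_peak_matrix(sim$interactions, file.path(out_dir, "peak_matrix.tsv"))
  write_regulatory_states(sim$reg_states, file.path(out_dir, "regulatory_states.tsv"))
  utils::write.table(sim$expression, file.path(out_dir, "expression.tsv"),
                     sep = "\t", quote = FALSE)
  write_gwas_table(gwas, file.path(out_dir, "gwas.tsv"))
  write_haplotypes(hp$panel, file.path(out_dir, "haplotypes.legend.tsv"),
                   file.path(out_dir, "haplotypes.matrix.txt"))
  write_recomb_map(hp$recomb_map, file.path(out_dir, "recomb_map.txt"))
  write_eqtl_table(eqtls, file.path(out_dir, "eqtls.tsv"))
  write_coding_annotation(coding, file.path(out_dir, "coding.tsv"))
  utils::write.table(sim$gene_models, file.path(out_dir, "gene_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(interactome = sim, haplotypes = hp, gwas = gwas,
                 eqtls = eqtls, causal = causal))
}

#' Simulate a blockshifter input dataset
#'
#' Builds a fragment map, clumped test/control PIR fragment sets and
#' SNP-level posterior masses, for calibration and power studies of the
#' blockshifter test. Under `enrichment = 1` the per-SNP masses are
#' exchangeable between labels (the null); larger values scale the masses
#' on test-set fragments.
#'
#' @param seed seed.
#' @param n_runs number of PIR runs (clumps) to plant.
#' @param mean_run_len mean fragments per run.
#' @param frac_test probability a PIR fragment is labeled test.
#' @param enrichment multiplicative mass enrichment on test fragments.
#' @param region_length,mean_fragment_len fragment map geometry.
#' @return list with `frag_map`, `test`, `control` (fragment ids) and
#'   `posteriors` (`chrom`, `pos`, `ppi`).
#' @export
sim_blockshifter_dataset <- function(seed, n_runs = 40, mean_run_len = 2,
                                     frac_test = 0.5, enrichment = 1,
                                     region_length = 3e6, mean_fragment_len = 4096) {
  cfg <- sim_config(seed = seed,
                    chrom_lengths = c(chr1 = region_length),
                    mean_fragment_len = mean_fragment_len)
  fm <- simulate_fragment_map(cfg, seed = derive_seed(seed, 11))
  withr::with_seed(derive_seed(seed, 12), {
    n <- nrow(fm)
    starts <- sort(sample.int(n - 10L, n_runs))
    pir <- integer(0)
    for (st in starts) {
      len <- 1L + stats::rpois(1, mean_run_len - 1)
      pir <- union(pir, st:min(st + len - 1L, n))
    }
    label_test <- stats::runif(length(pir)) < frac_test
    test <- pir[label_test]; control <- pir[!label_test]
    # one to three SNPs per PIR fragment with exchangeable exponential masses
    snp_frag <- rep(pir, times = 1L + stats::rpois(length(pir), 1))
    pos <- round(fm$start[snp_frag] +
                   stats::runif(length(snp_frag)) * (fm$end[snp_frag] - fm$start[snp_frag] - 1))
    ppi <- stats::rexp(length(snp_frag))
    ppi[snp_frag %in% test] <- ppi[snp_frag %in% test] * enrichment
    list(
      frag_map = fm, test = test, control = control,
      posteriors = data.frame(chrom = fm$chrom[snp_frag], pos = pos, ppi = ppi)
    )
  })
}
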