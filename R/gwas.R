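#' Filter spuriously strong GWAS associations
#'
#' Removes genome-wide-significant SNPs (p below `p_index`) that have no
#' supporting signal: a supporter is any other SNP with p below `p_support`
#' that is either in LD with the index SNP (r-squared above `r2_support`)
#' or within `window` bp of it. SNPs above the index threshold are never
#' dropped by this filter.
#'
#' @param gwas a `gwas_table` with a `snp_id` column matching the panel
#'   legend (rows absent from the panel rely on the distance arm only).
#' @param panel a [haplotype_panel()] for the LD arm.
#' @param p_index genome-wide significance threshold (default 5e-8).
#' @param p_support supporter p-value threshold (default 1e-5).
#' @param r2_support supporter LD threshold (default 0.6).
#' @param window supporter distance window in bp (default 50 kb).
#' @return the filtered `gwas_table`.
#' @export
qc_filter <- function(gwas, panel, p_index = 5e-8, p_support = 1e-5,
                      r2_support = 0.6, window = 5e4) {
  if (nrow(gwas) == 0L) return(gwas)
  drop <- rep(FALSE, nrow(gwas))
  idx <- which(!is.na(gwas$p) & gwas$p < p_index)
  for (i in idx) {
    others <- which(seq_len(nrow(gwas)) != i & !is.na(gwas$p) & gwas$p < p_support)
    if (length(others) == 0L) { drop[i] <- TRUE; next }
    same_chr <- norm_chrom(gwas$chrom[others]) == norm_chrom(gwas$chrom[i])
    near <- same_chr & abs(gwas$pos[others] - gwas$pos[i]) <= window
    if (any(near)) next
    supported <- FALSE
    pi <- match(gwas$snp_id[i], panel$legend$id)
    if (!is.na(pi) && stats::var(panel$H[pi, ]) > 0) {
      r2 <- r_squared_profile(panel, pi)
      oj <- match(gwas$snp_id[others[same_chr]], panel$legend$id)
      oj <- oj[!is.na(oj)]
      supported <- any(r2[oj] > r2_support, na.rm = TRUE)
    }
    if (!supported) drop[i] <- TRUE
  }
  gwas[!drop, , drop = FALSE]
}

#' Mask a genomic region from GWAS summary statistics
#'
#' Default is the MHC region (GRCh37 chr6:25-35 Mb), masked for its
#' extended LD and complex autoimmune associations.
#'
#' @param gwas a `gwas_table`.
#' @param chrom,start,end region to remove (bp, half-open).
#' @return the masked `gwas_table`.
#' @export
mask_region <- function(gwas, chrom = "chr6", start = 25e6, end = 35e6) {
  inside <- norm_chrom(gwas$chrom) == norm_chrom(chrom) &
    gwas$pos >= start & gwas$pos < end
  gwas[!inside, , drop = FALSE]
}

#' Partition the genome into recombination blocks
#'
#' Cuts the cumulative genetic map at multiples of `step` (default 0.1 cM);
#' block bp boundaries are linearly interpolated from the map. The final
#' block may span less than one step. Blocks tile the mapped region.
#'
#' @param recomb_map data.frame with `position` and cumulative `map` (cM).
#' @param step block width in cM.
#' @return data.frame with `block`, `start`, `end` (bp) and `start_cm`,
#'   `end_cm`.
#' @export
partition_blocks <- function(recomb_map, step = 0.1) {
  validate_recomb_map(recomb_map)
  total <- max(recomb_map$map) - min(recomb_map$map)
  n_blocks <- max(1L, ceiling(total / step - 1e-9))
  cm_cuts <- min(recomb_map$map) + step * seq_len(n_blocks - 1L)
  bp_cuts <- stats::approx(recomb_map$map, recomb_map$position, xout = cm_cuts,
                           ties = "ordered")$y
  edges_bp <- c(min(recomb_map$position), bp_cuts, max(recomb_map$position))
  edges_cm <- c(min(recomb_map$map), cm_cuts, max(recomb_map$map))
  data.frame(
    block = seq_len(n_blocks),
    start = edges_bp[-length(edges_bp)], end = edges_bp[-1L],
    start_cm = edges_cm[-length(edges_cm)], end_cm = edges_cm[-1L]
  )
}

# Block id covering each position (last block closed on the right).
assign_blocks <- function(pos, blocks) {
  k <- findInterval(pos, blocks$start)
  k[pos > max(blocks$end)] <- NA_integer_
  k[k < 1L] <- NA_integer_
  pmin(k, nrow(blocks))
}

#' LD-proxy transfer of p-values to untyped panel SNPs
#'
#' Within each recombination block, every panel SNP with minor allele
#' frequency above `maf_min` that lacks a study p-value is paired with the
#' study SNP of maximal r-squared in the block; if that maximum exceeds
#' `r2_min` the study p-value is copied over and the SNP flagged as
#' imputed, otherwise the SNP is discarded. Study SNPs absent from the
#' panel are discarded, as are all panel SNPs of a block containing no
#' study SNP (counted in the result's `log`).
#'
#' @param gwas a `gwas_table` with `snp_id`.
#' @param panel a [haplotype_panel()].
#' @param blocks block partition from [partition_blocks()].
#' @param r2_min pairing threshold (default 0.6).
#' @param maf_min panel MAF filter (default 0.01).
#' @return a `gwas_table` covering typed and imputed SNPs, with an
#'   `imputed` flag and attribute `log`.
#' @export
pmi_impute <- function(gwas, panel, blocks, r2_min = 0.6, maf_min = 0.01) {
  leg <- panel$legend
  maf <- panel_maf(panel)
  blk <- assign_blocks(leg$position, blocks)
  study_row <- match(leg$id, gwas$snp_id)
  typed <- !is.na(study_row) & !is.na(gwas$p[study_row])
  n_dropped_study <- sum(!gwas$snp_id %in% leg$id)

  keep <- list()
  log <- list(study_snps_not_in_panel = n_dropped_study,
              blocks_without_study_snps = 0L, discarded_low_ld = 0L)
  for (b in unique(blk[!is.na(blk)])) {
    i <- which(blk == b)
    ti <- i[typed[i]]
    mi <- i[!typed[i] & maf[i] > maf_min]
    if (length(ti) == 0L) {
      log$blocks_without_study_snps <- log$blocks_without_study_snps + 1L
      next
    }
    g <- gwas[study_row[ti], , drop = FALSE]
    g$snp_id <- leg$id[ti]
    g$imputed <- FALSE
    keep[[length(keep) + 1L]] <- g
    if (length(mi) == 0L) next
    Ht <- panel$H[ti, , drop = FALSE]
    vt <- apply(Ht, 1, stats::var)
    for (m in mi) {
      hm <- panel$H[m, ]
      if (stats::var(hm) == 0) next
      r2 <- rep(NA_real_, length(ti))
      r2[vt > 0] <- as.vector(stats::cor(hm, t(Ht[vt > 0, , drop = FALSE])))^2
      jmax <- which.max(r2)
      if (length(jmax) == 0L || is.na(r2[jmax]) || r2[jmax] <= r2_min) {
        log$discarded_low_ld <- log$discarded_low_ld + 1L
        next
      }
      src <- gwas[study_row[ti[jmax]], , drop = FALSE]
      src$snp_id <- leg$id[m]
      src$pos <- leg$position[m]
      src$maf <- maf[m]
      src$imputed <- TRUE
      keep[[length(keep) + 1L]] <- src
    }
  }
  out <- do.call(rbind, keep)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "log") <- log
  class(out) <- c("gwas_table", "data.frame")
  out
}

#' Fill missing minor allele frequencies from the reference panel
#'
#' GWAS summary tables sometimes omit allele frequencies; when a SNP is
#' present in the haplotype panel its MAF is computed from the panel
#' haplotypes instead.
#'
#' @param gwas a `gwas_table` with a `snp_id` column.
#' @param panel a [haplotype_panel()].
#' @return the table with `maf` filled where it was missing.
#' @export
add_panel_maf <- function(gwas, panel) {
  missing_maf <- is.na(gwas$maf)
  if (!any(missing_maf)) return(gwas)
  idx <- match(gwas$snp_id[missing_maf], panel$legend$id)
  gwas$maf[missing_maf] <- panel_maf(panel)[idx]
  gwas
}
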