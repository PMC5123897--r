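#' Interaction sets
#'
#' Container for bait/other-end restriction-fragment pairs with one CHiCAGO
#' score per cell type. High-confidence interactions are those with a score
#' of at least 5 in at least one cell type.
#'
#' @param pairs data.frame with columns `bait_chr`, `bait_start`, `bait_end`,
#'   `bait_id`, `bait_name`, `oe_chr`, `oe_start`, `oe_end`, `oe_id`,
#'   `oe_name`, `dist`. Coordinates 0-based half-open; `dist` is the signed
#'   distance from the bait midpoint to the other-end midpoint and is `NA`
#'   for trans (inter-chromosomal) pairs.
#' @param scores numeric matrix (rows = interactions) of non-negative CHiCAGO
#'   scores, one column per cell type.
#' @return An object of class `interaction_set` with elements `pairs`,
#'   `scores` and `cell_types`.
#' @export
interaction_set <- function(pairs, scores) {
  scores <- as.matrix(scores)
  if (nrow(pairs) != nrow(scores)) {
    stop_format("pairs and scores must have the same number of rows")
  }
  if (any(scores < 0, na.rm = TRUE)) stop_format("CHiCAGO scores must be non-negative")
  cis <- norm_chrom(pairs$bait_chr) == norm_chrom(pairs$oe_chr)
  if (any(cis & is.na(pairs$dist)) || any(!cis & !is.na(pairs$dist))) {
    stop_format("dist must be defined exactly for cis pairs")
  }
  structure(
    list(pairs = pairs, scores = scores, cell_types = colnames(scores)),
    class = "interaction_set"
  )
}

#' @export
print.interaction_set <- function(x, ...) {
  hc <- sum(apply(x$scores >= 5, 1, any))
  cat(sprintf(
    "Interaction set: %d fragment pairs x %d cell types (%d high-confidence, score >= 5)\n",
    nrow(x$pairs), length(x$cell_types), hc
  ))
  invisible(x)
}

#' Number of interactions in a set
#' @param x an `interaction_set`.
#' @export
n_interactions <- function(x) nrow(x$pairs)

peak_matrix_cols <- c(
  "baitChr", "baitStart", "baitEnd", "baitID", "baitName",
  "oeChr", "oeStart", "oeEnd", "oeID", "oeName", "dist"
)

#' Read and write a PCHi-C peak matrix
#'
#' The peak matrix is a TSV with the columns `baitChr baitStart baitEnd
#' baitID baitName oeChr oeStart oeEnd oeID oeName dist` followed by one
#' CHiCAGO score column per cell type. Starts in the file are 1-based
#' inclusive and are converted to the package's 0-based half-open convention
#' on read. `dist` is re-derived from the fragment midpoints for cis rows and
#' checked against the file; trans rows carry `NA`.
#'
#' @param path file path.
#' @return `read_peak_matrix` returns an [interaction_set()].
#' @export
read_peak_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(peak_matrix_cols, names(df))
  if (length(missing) > 0L) {
    stop_format("peak matrix is missing column(s): %s", paste(missing, collapse = ", "))
  }
  score_cols <- setdiff(names(df), peak_matrix_cols)
  if (length(score_cols) == 0L) stop_format("peak matrix has no score columns")
  scores <- as.matrix(df[, score_cols, drop = FALSE])
  if (any(scores < 0, na.rm = TRUE)) stop_format("negative CHiCAGO score in %s", path)
  pairs <- data.frame(
    bait_chr = as.character(df$baitChr),
    bait_start = df$baitStart - 1, bait_end = df$baitEnd,
    bait_id = df$baitID, bait_name = as.character(df$baitName),
    oe_chr = as.character(df$oeChr),
    oe_start = df$oeStart - 1, oe_end = df$oeEnd,
    oe_id = df$oeID, oe_name = as.character(df$oeName),
    dist = df$dist, stringsAsFactors = FALSE
  )
  cis <- norm_chrom(pairs$bait_chr) == norm_chrom(pairs$oe_chr)
  expected <- (pairs$oe_start + pairs$oe_end) / 2 - (pairs$bait_start + pairs$bait_end) / 2
  pairs$dist[!cis] <- NA_real_
  bad <- cis & (is.na(pairs$dist) | abs(pairs$dist - expected) > 1)
  if (any(bad)) {
    stop_format("dist column disagrees with fragment coordinates for %d cis row(s)", sum(bad))
  }
  interaction_set(pairs, scores)
}

#' @rdname read_peak_matrix
#' @param x an `interaction_set`.
#' @export
write_peak_matrix <- function(x, path) {
  p <- x$pairs
  df <- data.frame(
    baitChr = p$bait_chr, baitStart = p$bait_start + 1, baitEnd = p$bait_end,
    baitID = p$bait_id, baitName = p$bait_name,
    oeChr = p$oe_chr, oeStart = p$oe_start + 1, oeEnd = p$oe_end,
    oeID = p$oe_id, oeName = p$oe_name, dist = p$dist,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  df <- cbind(df, as.data.frame(x$scores))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' TSV with columns `chrom pos a1 a2 maf p` and optionally `beta`, `se`, `n`,
#' `cc_ratio` (case proportion for case-control traits). An empty table is
#' returned as an empty data frame, not an error.
#'
#' @param path file path.
#' @param chroms optional character vector of known chromosomes; rows on
#'   other chromosomes raise an error.
#' @return data.frame of class `gwas_table` with an `imputed` flag column.
#' @export
read_gwas_table <- function(path, chroms = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "a1", "a2", "maf", "p")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L) {
    stop_format("GWAS table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  df$chrom <- as.character(df$chrom)
  if (!is.null(chroms) && nrow(df) > 0L) {
    bad <- !norm_chrom(df$chrom) %in% norm_chrom(chroms)
    if (any(bad)) stop_format("unknown chromosome(s): %s", paste(unique(df$chrom[bad]), collapse = ", "))
  }
  if (nrow(df) > 0L) {
    ok_p <- is.na(df$p) | (df$p > 0 & df$p <= 1)
    if (!all(ok_p)) stop_format("p-values must lie in (0, 1]")
    if (any(df$maf <= 0, na.rm = TRUE)) stop_format("maf must be positive")
  }
  if (is.null(df$imputed)) df$imputed <- rep(FALSE, nrow(df))
  class(df) <- c("gwas_table", "data.frame")
  df
}

#' @rdname read_gwas_table
#' @param x a `gwas_table`.
#' @export
write_gwas_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a recombination map
#'
#' HapMap dialect: whitespace-separated columns `position rate(cM/Mb)
#' map(cM)`. The cumulative map must be non-decreasing.
#'
#' @param path file path.
#' @return data.frame with columns `position`, `rate`, `map`.
#' @export
read_recomb_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop_format("recombination map needs 3 columns: position, rate, map")
  df <- stats::setNames(df[, 1:3], c("position", "rate", "map"))
  validate_recomb_map(df)
  df
}

validate_recomb_map <- function(df) {
  if (is.unsorted(df$position, strictly = TRUE)) {
    stop_format("recombination map positions must be strictly increasing")
  }
  if (any(diff(df$map) < 0)) {
    stop_format("cumulative genetic map must be non-decreasing")
  }
  invisible(df)
}

#' @rdname read_recomb_map
#' @param x a recombination map data.frame.
#' @export
write_recomb_map <- function(x, path) {
  utils::write.table(x, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference haplotype panels
#'
#' IMPUTE-style representation: a legend (`id position a0 a1`) plus a 0/1
#' matrix with one row per SNP and one column per haplotype.
#'
#' @param legend data.frame with columns `id`, `position`, `a0`, `a1`.
#' @param H 0/1 matrix, SNPs x haplotypes.
#' @param chrom chromosome the panel covers.
#' @return object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(legend, H, chrom = "chr1") {
  H <- as.matrix(H)
  if (nrow(legend) != nrow(H)) {
    stop_format("legend has %d SNPs but haplotype matrix has %d rows", nrow(legend), nrow(H))
  }
  if (!all(H %in% c(0L, 1L))) stop_format("haplotype matrix entries must be 0/1")
  structure(
    list(legend = legend, H = H, chrom = chrom),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "Haplotype panel: %d SNPs x %d haplotypes (%s)\n",
    nrow(x$H), ncol(x$H), x$chrom
  ))
  invisible(x)
}

#' @rdname haplotype_panel
#' @param legend_path,matrix_path file paths for the legend TSV and the
#'   whitespace-separated 0/1 matrix.
#' @export
read_haplotypes <- function(legend_path, matrix_path, chrom = "chr1") {
  legend <- utils::read.delim(legend_path, stringsAsFactors = FALSE)
  H <- as.matrix(utils::read.table(matrix_path, header = FALSE))
  dimnames(H) <- NULL
  haplotype_panel(legend, H, chrom = chrom)
}

#' @rdname haplotype_panel
#' @param x a `haplotype_panel`.
#' @export
write_haplotypes <- function(x, legend_path, matrix_path) {
  utils::write.table(x$legend, legend_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$H, matrix_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(legend_path)
}

#' Squared allelic correlation (LD) between two panel SNPs
#'
#' r-squared is the squared Pearson correlation of the two 0/1 haplotype
#' rows; both SNPs must be polymorphic in the panel.
#'
#' @param panel a [haplotype_panel()].
#' @param i,j SNP row indices or legend ids.
#' @return numeric in `[0, 1]`.
#' @export
r_squared <- function(panel, i, j) {
  idx <- function(k) {
    if (is.character(k)) match(k, panel$legend$id) else as.integer(k)
  }
  i <- idx(i); j <- idx(j)
  xi <- panel$H[i, ]; xj <- panel$H[j, ]
  if (stats::var(xi) == 0 || stats::var(xj) == 0) {
    stop_format("LD is undefined for monomorphic SNPs")
  }
  stats::cor(xi, xj)^2
}

# r^2 of one SNP against every row of the panel; NA where the partner is
# monomorphic.
r_squared_profile <- function(panel, i) {
  if (is.character(i)) i <- match(i, panel$legend$id)
  xi <- panel$H[i, ]
  f <- rowMeans(panel$H)
  if (f[i] == 0 || f[i] == 1) stop_format("LD is undefined for monomorphic SNPs")
  poly <- f > 0 & f < 1
  out <- rep(NA_real_, nrow(panel$H))
  out[poly] <- as.vector(stats::cor(xi, t(panel$H[poly, , drop = FALSE])))^2
  out
}

#' Minor allele frequencies of a haplotype panel
#' @param panel a [haplotype_panel()].
#' @export
panel_maf <- function(panel) {
  f <- rowMeans(panel$H)
  pmin(f, 1 - f)
}

#' Read regulatory feature states
#'
#' BED-like TSV (0-based half-open, with a header): `chrom start end name
#' score strand feature_class` followed by one activity column per cell type
#' with values in `active`, `poised`, `repressed`, `inactive`.
#'
#' @param path file path.
#' @param cell_types optional cell types to require.
#' @return data.frame of class `regulatory_states`; the activity columns are
#'   recorded in `attr(, "cell_types")`.
#' @export
read_regulatory_states <- function(path, cell_types = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("chrom", "start", "end", "name", "score", "strand", "feature_class")
  missing <- setdiff(fixed, names(df))
  if (length(missing) > 0L) {
    stop_format("regulatory state table missing column(s): %s", paste(missing, collapse = ", "))
  }
  act_cols <- setdiff(names(df), fixed)
  if (!is.null(cell_types)) {
    missing_ct <- setdiff(cell_types, act_cols)
    if (length(missing_ct) > 0L) {
      stop_format("no activity column for cell type(s): %s", paste(missing_ct, collapse = ", "))
    }
  }
  states <- c("active", "poised", "repressed", "inactive")
  for (ct in act_cols) {
    if (!all(df[[ct]] %in% states)) {
      stop_format("invalid activity state in column %s", ct)
    }
  }
  attr(df, "cell_types") <- act_cols
  class(df) <- c("regulatory_states", "data.frame")
  df
}

#' @rdname read_regulatory_states
#' @param x a `regulatory_states` table.
#' @export
write_regulatory_states <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an eQTL results table
#'
#' TSV `gene_id snp_id p fdr_pass lead`; at most one lead SNP per gene.
#'
#' @param path file path.
#' @return data.frame of class `eqtl_table`.
#' @export
read_eqtl_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "snp_id", "p", "fdr_pass", "lead")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L) {
    stop_format("eQTL table missing column(s): %s", paste(missing, collapse = ", "))
  }
  df$fdr_pass <- as.logical(df$fdr_pass)
  df$lead <- as.logical(df$lead)
  leads <- table(df$gene_id[df$lead])
  if (any(leads > 1L)) {
    stop_format("more than one lead eQTL for gene(s): %s",
                paste(names(leads)[leads > 1L], collapse = ", "))
  }
  class(df) <- c("eqtl_table", "data.frame")
  df
}

#' @rdname read_eqtl_table
#' @param x an `eqtl_table`.
#' @export
write_eqtl_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a coding-consequence annotation table
#'
#' VEP-style output reduced to `snp_id gene_id consequence`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_coding_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("snp_id", "gene_id", "consequence")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L) {
    stop_format("coding annotation missing column(s): %s", paste(missing, collapse = ", "))
  }
  df
}

#' @rdname read_coding_annotation
#' @param x a coding annotation data.frame.
#' @export
write_coding_annotation <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
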