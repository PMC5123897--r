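#' Cell-type distance weights
#'
#' Pairwise Euclidean distances between the cell-type columns of the
#' complete dataset (all interactions' scores, or all genes' expression
#' values). The weights down-weight near-duplicate cell types (for example
#' several macrophage preparations) when computing specificity scores, so
#' that over-represented lineages do not deflate each other's scores.
#'
#' @param full_data numeric matrix, items x cell types.
#' @return symmetric non-negative matrix of inter-cell-type distances with a
#'   zero diagonal.
#' @export
distance_weights <- function(full_data) {
  full_data <- as.matrix(full_data)
  if (ncol(full_data) < 2L) stop_format("distance weights need at least 2 cell types")
  as.matrix(stats::dist(t(full_data)))
}

#' Specificity score of a quantitative profile
#'
#' For a profile `x` over cell types and a cell type `c`, the specificity
#' score is the weighted mean of the differences `x_c - x_i` over the other
#' cell types, with weights `d_{c,i}` taken from [distance_weights()]:
#' `s_c = sum_{i != c} d_{c,i} (x_c - x_i) / sum_{i != c} d_{c,i}`.
#' The score is translation invariant and scales linearly with `x`; a
#' constant profile scores 0 in every cell type.
#'
#' @param x numeric profile over cell types (one value per cell type), or a
#'   matrix (rows = items) for `specificity_scores`.
#' @param weights distance-weight matrix as from [distance_weights()].
#' @param cell index or name of the cell type `c`.
#' @return `specificity_score` returns one number; `specificity_scores`
#'   returns the score for every cell type (a vector, or a matrix for matrix
#'   input).
#' @export
specificity_score <- function(x, weights, cell) {
  if (is.character(cell)) cell <- match(cell, colnames(weights))
  w <- weights[cell, -cell]
  if (sum(w) <= 0) stop_format("specificity score undefined: all weights are zero")
  sum(w * (x[cell] - x[-cell])) / sum(w)
}

#' @rdname specificity_score
#' @export
specificity_scores <- function(x, weights) {
  if (is.matrix(x)) {
    return(t(apply(x, 1, specificity_scores, weights = weights)))
  }
  vapply(seq_along(x), function(c) specificity_score(x, weights, c), numeric(1))
}

#' Cluster specificity scores
#'
#' The profile of a cluster of interactions is the mean asinh-transformed
#' CHiCAGO score per cell type over the cluster's members; specificity
#' scores are then computed against distance weights derived from the full
#' score dataset.
#'
#' @param cluster_scores score matrix of the cluster's interactions (rows) by
#'   cell type.
#' @param weights distance weights from the complete dataset.
#' @return named vector of specificity scores per cell type.
#' @export
cluster_specificity <- function(cluster_scores, weights) {
  x <- colMeans(asinh(as.matrix(cluster_scores)))
  stats::setNames(specificity_scores(x, weights), colnames(cluster_scores))
}

# Activity of the other end of each interaction, per cell type: TRUE where
# the fragment overlaps at least one regulatory feature in the "active"
# state for that cell type.
oe_activity_matrix <- function(ints, reg_states, cell_types,
                               classes = c("promoter", "proximal_enhancer", "distal_enhancer")) {
  feat <- reg_states[reg_states$feature_class %in% classes, , drop = FALSE]
  out <- matrix(FALSE, nrow(ints$pairs), length(cell_types),
                dimnames = list(NULL, cell_types))
  for (ct in cell_types) {
    act <- feat[feat[[ct]] == "active", , drop = FALSE]
    out[, ct] <- overlaps_any(
      ints$pairs$oe_chr, ints$pairs$oe_start, ints$pairs$oe_end,
      act$chrom, act$start, act$end
    )
  }
  out
}

#' Gene specificity scores from interactions with active enhancers
#'
#' Interactions are retained when (i) their bait maps exclusively to a
#' unique protein-coding gene promoter and (ii) at least one cell type has
#' both a CHiCAGO score at or above the threshold and an active enhancer at
#' the other end. For retained interactions, scores are set to zero in cell
#' types where the enhancer is not active, asinh-transformed and capped at
#' `cap` (4.3, equivalent to a raw score of about 36.8), giving "processed"
#' scores. Per-interaction specificity scores (weights from the full
#' asinh-capped score dataset) are averaged within genes.
#'
#' @param ints an [interaction_set()].
#' @param reg_states a `regulatory_states` table.
#' @param gene_models data.frame with `gene_id`, `bait_frag` and a `coding`
#'   flag.
#' @param score_threshold high-confidence CHiCAGO threshold (default 5).
#' @param cap cap on asinh-transformed scores (default 4.3).
#' @return list of class `gene_specificity` with `s` (genes x cell types),
#'   `n_g` (qualifying interactions per gene), `weights`, the retained row
#'   indices, and `excluded_genes`.
#' @export
gene_specificity_matrix <- function(ints, reg_states, gene_models,
                                    score_threshold = 5, cap = 4.3) {
  ct <- ints$cell_types
  # baits mapping exclusively to one protein-coding gene
  coding_gm <- gene_models[gene_models$coding, , drop = FALSE]
  bait_genes <- table(coding_gm$bait_frag)
  multi <- as.numeric(names(bait_genes)[bait_genes > 1L])
  gm <- coding_gm[!coding_gm$bait_frag %in% multi, , drop = FALSE]
  gene_of_row <- gm$gene_id[match(ints$pairs$bait_id, gm$bait_frag)]

  active <- oe_activity_matrix(ints, reg_states, ct)
  qual <- !is.na(gene_of_row) &
    apply(ints$scores >= score_threshold & active, 1, any)

  processed_full <- pmin(asinh(ints$scores), cap)
  weights <- distance_weights(processed_full)

  sc <- ints$scores[qual, , drop = FALSE]
  sc[!active[qual, , drop = FALSE]] <- 0
  processed <- pmin(asinh(sc), cap)
  s_int <- specificity_scores(processed, weights)

  genes <- unique(gene_of_row[qual])
  s <- matrix(0, length(genes), length(ct), dimnames = list(genes, ct))
  n_g <- integer(length(genes))
  gq <- gene_of_row[qual]
  for (k in seq_along(genes)) {
    rows <- which(gq == genes[k])
    n_g[k] <- length(rows)
    s[k, ] <- colMeans(s_int[rows, , drop = FALSE])
  }
  excluded <- setdiff(gm$gene_id, genes)
  structure(
    list(s = s, n_g = stats::setNames(n_g, genes), weights = weights,
         rows = which(qual), excluded_genes = excluded),
    class = "gene_specificity"
  )
}

#' @export
print.gene_specificity <- function(x, ...) {
  cat(sprintf(
    "Gene specificity scores: %d genes x %d cell types (%d interactions used, %d genes excluded)\n",
    nrow(x$s), ncol(x$s), length(x$rows), length(x$excluded_genes)
  ))
  invisible(x)
}

#' Expression-based gene specificity scores
#'
#' Profiles are asinh-transformed expression values; distance weights come
#' from the full asinh-transformed expression dataset.
#'
#' @param expr expression matrix, genes x cell types.
#' @return matrix of specificity scores, genes x cell types.
#' @export
expression_specificity <- function(expr) {
  x <- asinh(as.matrix(expr))
  specificity_scores(x, distance_weights(x))
}

#' Cluster enrichment scores for cell-type-specific gene sets
#'
#' For each cell type `c`, `G_c` is the set of the most specifically
#' expressed genes (typically 100). With `p_{c,k}` the proportion of `G_c`
#' in cluster `k` and `q_k` the proportion of all analyzed genes in cluster
#' `k`, the enrichment score is `e_{c,k} = p_{c,k} - q_k`; `q_k` is the
#' expected value of `p_{c,k}` for a random gene draw.
#'
#' @param clusters named vector mapping gene id to cluster label.
#' @param top_sets named list: cell type -> character vector of gene ids.
#' @return list of class `cluster_enrichment` with matrices `e`, `p` and
#'   vector `q`.
#' @export
cluster_enrichment <- function(clusters, top_sets) {
  ks <- sort(unique(clusters))
  q <- as.vector(table(factor(clusters, levels = ks))) / length(clusters)
  names(q) <- ks
  p <- t(vapply(top_sets, function(g) {
    cl <- clusters[g]
    as.vector(table(factor(cl, levels = ks))) / length(g)
  }, numeric(length(ks))))
  colnames(p) <- ks
  structure(list(e = sweep(p, 2, q), p = p, q = q), class = "cluster_enrichment")
}

#' @export
print.cluster_enrichment <- function(x, ...) {
  cat(sprintf("Cluster enrichment scores: %d cell types x %d clusters\n",
              nrow(x$e), ncol(x$e)))
  invisible(x)
}

#' Permutation test for shared specificity of a bait's interactions
#'
#' Each interaction inherits a specificity value: the maximum over cell
#' types of its cluster's specificity scores. The statistic is the variance
#' of these values across the interactions of each bait (baits with a single
#' interaction are excluded); the null is obtained by permuting the
#' interaction-to-cluster labels. If promoters preferentially carry
#' interactions of similar cell-type specificity, observed variances fall
#' below the permuted ones.
#'
#' @param ints an [interaction_set()].
#' @param clusters cluster label per interaction.
#' @param n_perm number of label permutations.
#' @param seed seed.
#' @return list of class `bait_variance_test` with per-bait observed
#'   variances, permuted mean variances, and a one-sided permutation p-value
#'   for a downward shift of the mean variance.
#' @export
bait_specificity_variance_test <- function(ints, clusters, n_perm = 1000, seed) {
  weights <- distance_weights(asinh(ints$scores))
  labs <- sort(unique(clusters))
  max_s <- vapply(labs, function(k) {
    max(cluster_specificity(ints$scores[clusters == k, , drop = FALSE], weights))
  }, numeric(1))
  val <- max_s[match(clusters, labs)]

  baits <- ints$pairs$bait_id
  keep <- baits %in% names(which(table(baits) >= 2L))
  bait_var <- function(v) {
    as.vector(tapply(v[keep], baits[keep], stats::var))
  }
  obs <- bait_var(val)
  null_means <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      mean(bait_var(val[sample.int(length(val))]))
    }, numeric(1))
  })
  p <- (1 + sum(null_means <= mean(obs))) / (1 + n_perm)
  structure(
    list(observed = obs, observed_mean = mean(obs), null_means = null_means,
         p = p, n_perm = n_perm),
    class = "bait_variance_test"
  )
}

#' @export
print.bait_variance_test <- function(x, ...) {
  cat(sprintf(
    "Bait specificity variance test: observed mean %.4f vs null mean %.4f (p = %.4g, %d permutations)\n",
    x$observed_mean, mean(x$null_means), x$p, x$n_perm
  ))
  invisible(x)
}

#' k-means partition with multiple restarts
#'
#' Euclidean k-means with the best-inertia solution over `n_starts`
#' restarts; deterministic given the seed. Defaults mirror the gene
#' specificity clustering: 12 clusters and 10,000 random starts (pass a
#' smaller `n_starts` for quick work).
#'
#' @param x numeric matrix (rows are clustered).
#' @param k number of clusters.
#' @param n_starts random restarts.
#' @param seed seed.
#' @param iter_max maximum iterations per start.
#' @return list with `cluster` (named assignment) and `tot_withinss`.
#' @export
kmeans_partition <- function(x, k = 12, n_starts = 10000, seed, iter_max = 10000) {
  withr::with_seed(seed, {
    fit <- stats::kmeans(x, centers = k, nstart = n_starts, iter.max = iter_max)
    list(cluster = stats::setNames(fit$cluster, rownames(x)),
         tot_withinss = fit$tot.withinss)
  })
}
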