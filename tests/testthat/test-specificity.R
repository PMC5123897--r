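test_that("distance weights are Euclidean distances between cell-type columns", {
  m <- cbind(a = c(0, 0), b = c(3, 4))
  w <- distance_weights(m)
  expect_equal(w["a", "b"], 5)
  expect_equal(diag(w), c(a = 0, b = 0))
  expect_equal(distance_weights(cbind(x = 1:3, y = 1:3))["x", "y"], 0)
  set.seed(1)
  r <- matrix(rnorm(40), ncol = 4)
  expect_equal(distance_weights(r), t(distance_weights(r)))
  expect_error(distance_weights(matrix(1:3, ncol = 1)), "2 cell types")
})

test_that("specificity score matches its closed form and brute force", {
  w_eq <- matrix(1, 3, 3); diag(w_eq) <- 0
  expect_equal(specificity_scores(c(2, 0, 0), w_eq), c(2, -1, -1))
  expect_equal(specificity_scores(c(4, 4, 4), w_eq), c(0, 0, 0))

  # two cell types: s1 = x1 - x2 for any positive weight
  w2 <- matrix(c(0, 7, 7, 0), 2, 2)
  expect_equal(specificity_scores(c(3, 1), w2), c(2, -2))

  # brute-force agreement to 1e-12 on random fixtures
  set.seed(2)
  for (rep in 1:10) {
    x <- rnorm(6)
    W <- as.matrix(dist(matrix(rnorm(30), ncol = 6) |> t()))
    expect_equal(specificity_scores(x, W), brute_specificity(x, W),
                 tolerance = 1e-12)
  }

  # translation invariance and linear scaling
  x <- rnorm(6); W <- as.matrix(dist(diag(6) + 1))
  expect_equal(specificity_scores(x + 5, W), specificity_scores(x, W))
  expect_equal(specificity_scores(3 * x, W), 3 * specificity_scores(x, W))

  expect_error(specificity_score(c(1, 2), matrix(0, 2, 2), 1), "weights are zero")
})

test_that("cluster specificity is a mean-profile score", {
  set.seed(3)
  scores <- matrix(rexp(40, 1 / 4), ncol = 4,
                   dimnames = list(NULL, c("a", "b", "c", "d")))
  w <- distance_weights(asinh(scores))
  one <- cluster_specificity(scores[3, , drop = FALSE], w)
  expect_equal(unname(one), specificity_scores(asinh(scores[3, ]), w))
  dup <- cluster_specificity(scores[c(1:4, 1:4), ], w)
  expect_equal(dup, cluster_specificity(scores[1:4, ], w))
})

test_that("gene specificity applies filtering, zeroing and the 4.3 cap", {
  # the cap corresponds to a raw score of about 36.8
  expect_equal(sinh(4.3), 36.8, tolerance = 2e-3)
  expect_lt(asinh(36.8), 4.3)
  expect_equal(pmin(asinh(100), 4.3), 4.3)

  fm <- toy_fragment_map(40, 2000)
  ct <- c("Mon", "nCD4")
  scores <- rbind(
    c(10, 0.5),   # G1 int 1: hc in Mon
    c(100, 6),    # G1 int 2: hc in both; raw 100 must cap
    c(8, 7),      # G2: bait shared by two genes -> filtered out
    c(0.5, 1)     # G3: never high-confidence -> filtered out
  )
  colnames(scores) <- ct
  ints <- toy_interactions(fm, c(5, 5, 20, 30), c(10, 15, 25, 35), scores)
  gene_models <- data.frame(
    gene_id = c("G1", "G2a", "G2b", "G3"),
    bait_frag = c(5, 20, 20, 30),
    coding = TRUE
  )
  # enhancers active everywhere on the used other ends
  act <- matrix("active", 3, 2, dimnames = list(NULL, ct))
  reg <- toy_reg_states(rep("chr1", 3), fm$start[c(10, 15, 25)] + 100,
                        fm$end[c(10, 15, 25)] - 100,
                        rep("distal_enhancer", 3), act)
  gs <- gene_specificity_matrix(ints, reg, gene_models)
  expect_equal(rownames(gs$s), "G1")
  expect_equal(unname(gs$n_g), 2L)

  # hand-computed expectation: processed scores, per-interaction specificity,
  # averaged over the gene's two interactions
  processed_full <- pmin(asinh(scores), 4.3)
  w <- distance_weights(processed_full)
  p1 <- pmin(asinh(scores[1, ]), 4.3)
  p2 <- pmin(asinh(scores[2, ]), 4.3)
  expect_equal(p2[["Mon"]], 4.3)  # capped
  manual <- (brute_specificity(p1, w) + brute_specificity(p2, w)) / 2
  expect_equal(unname(gs$s["G1", ]), manual, tolerance = 1e-12)

  # zeroing: inactive enhancer in nCD4 zeroes that cell type's score
  act2 <- act; act2[, "nCD4"] <- "inactive"
  reg2 <- toy_reg_states(rep("chr1", 3), fm$start[c(10, 15, 25)] + 100,
                         fm$end[c(10, 15, 25)] - 100,
                         rep("distal_enhancer", 3), act2)
  gs2 <- gene_specificity_matrix(ints, reg2, gene_models)
  z1 <- p1; z1[["nCD4"]] <- 0
  z2 <- p2; z2[["nCD4"]] <- 0
  manual2 <- (brute_specificity(z1, w) + brute_specificity(z2, w)) / 2
  expect_equal(unname(gs2$s["G1", ]), manual2, tolerance = 1e-12)
})

test_that("expression specificity matches brute force on a 5-gene fixture", {
  set.seed(4)
  expr <- matrix(rexp(20, 1 / 10), nrow = 5,
                 dimnames = list(paste0("G", 1:5), c("a", "b", "c", "d")))
  s <- expression_specificity(expr)
  W <- distance_weights(asinh(expr))
  for (g in 1:5) {
    expect_equal(unname(s[g, ]), brute_specificity(asinh(expr[g, ]), W),
                 tolerance = 1e-12)
  }
  # constant expression scores zero; exclusive expression peaks in its cell type
  expr2 <- rbind(expr, ubiq = rep(7, 4), excl = c(0, 0, 50, 0))
  s2 <- expression_specificity(expr2)
  expect_equal(unname(s2["ubiq", ]), rep(0, 4))
  expect_equal(unname(which.max(s2["excl", ])), 3L)
})

test_that("cluster enrichment scores are proportion differences", {
  clusters <- setNames(rep(1:4, times = c(10, 40, 30, 20)), paste0("G", 1:100))
  # top set entirely inside cluster 1 (q1 = 0.1)
  e <- cluster_enrichment(clusters, list(c1 = paste0("G", 1:10)))
  expect_equal(unname(e$e["c1", "1"]), 0.9)
  expect_equal(unname(e$q), c(0.1, 0.4, 0.3, 0.2))
  expect_equal(sum(e$e["c1", ]), 0)  # rows of p and q both sum to 1

  # random 10-gene draws have mean enrichment zero
  set.seed(5)
  means <- replicate(400, {
    e <- cluster_enrichment(clusters, list(x = sample(names(clusters), 10)))
    e$e["x", "2"]
  })
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)) + 1e-12)
})

test_that("bait specificity variance test detects shared specificity", {
  # planted: each bait's interactions all come from the same cluster
  cfg <- sim_config(seed = 61, chrom_lengths = c(chr1 = 3e6), n_genes = 30)
  sim <- simulate_interactome(cfg)
  ints <- sim$interactions
  bait <- ints$pairs$bait_id
  shared <- unsplit(lapply(split(sim$truth$cluster, bait),
                           function(v) rep(v[1], length(v))), bait)
  res <- bait_specificity_variance_test(ints, shared, n_perm = 500, seed = 9)
  expect_lt(res$p, 0.05)
  expect_lt(res$observed_mean, mean(res$null_means))

  # permuted labels as observed: p roughly uniform over seeds
  set.seed(10)
  ps <- vapply(1:30, function(s) {
    labs <- sample(shared)
    bait_specificity_variance_test(ints, labs, n_perm = 60, seed = s)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)

  # single-interaction baits are excluded from the statistic
  keep <- bait %in% names(which(table(bait) >= 2))
  expect_equal(length(res$observed), length(unique(bait[keep])))
})

test_that("k-means partition recovers separated blobs deterministically", {
  set.seed(11)
  x <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 8), ncol = 2))
  rownames(x) <- paste0("G", 1:40)
  part <- kmeans_partition(x, k = 2, n_starts = 5, seed = 1)
  expect_equal(length(unique(part$cluster[1:20])), 1L)
  expect_equal(length(unique(part$cluster[21:40])), 1L)
  expect_identical(part, kmeans_partition(x, k = 2, n_starts = 5, seed = 1))

  # inertia never increases with more restarts
  set.seed(12)
  y <- matrix(rnorm(300), ncol = 3)
  w1 <- kmeans_partition(y, k = 6, n_starts = 1, seed = 2)$tot_withinss
  w10 <- kmeans_partition(y, k = 6, n_starts = 10, seed = 2)$tot_withinss
  expect_lte(w10, w1 + 1e-9)
})
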