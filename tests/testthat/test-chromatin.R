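# Two-domain contact matrix: within-domain contacts rich, across poor.
two_domain_matrix <- function(n_bins = 300, boundary = 150, within = 10, across = 1) {
  dom <- c(rep(1, boundary), rep(2, n_bins - boundary))
  outer(dom, dom, function(a, b) ifelse(a == b, within, across))
}

test_that("directionality index sign and symmetry behave as defined", {
  sym <- matrix(3, 120, 120)
  di <- compute_di(sym)
  expect_true(all(di$di == 0))
  expect_equal(nrow(call_tads(di)), 1L)  # flat track: no boundaries

  # planted two-domain matrix: DI negative approaching the boundary, then positive
  M <- two_domain_matrix()
  di2 <- compute_di(M)
  b <- 150
  expect_lt(di2$smooth[b - 4], 0)
  expect_gt(di2$smooth[b + 4], 0)
})

test_that("TAD caller recovers a planted boundary within one 25-kb bin", {
  M <- two_domain_matrix(n_bins = 300, boundary = 150)
  di <- compute_di(M)                      # 5-kb bins
  tads <- call_tads(di)
  bounds <- attr(tads, "boundaries")
  expect_equal(length(bounds), 1L)
  expect_lt(abs(bounds - 150 * 5000), 25000)

  # raising the extremum threshold to infinity removes all boundaries
  none <- call_tads(di, z_threshold = Inf)
  expect_equal(length(attr(none, "boundaries")), 0L)
})

test_that("replicate TAD merging averages matched boundaries and drops the rest", {
  rep1 <- structure(data.frame(chrom = "chr1", start = c(0, 1.0e6),
                               end = c(1.0e6, 2.0e6)),
                    class = c("tad_set", "data.frame"))
  rep2 <- structure(data.frame(chrom = "chr1", start = c(0, 1.1e6),
                               end = c(1.1e6, 2.0e6)),
                    class = c("tad_set", "data.frame"))
  merged <- merge_replicate_tads(list(rep1, rep2))
  expect_equal(merged$end[1], 1.05e6)   # mean of 1.00 and 1.10 Mb
  expect_equal(merged$start[2], 1.05e6)

  expect_equal(merge_replicate_tads(list(rep1, rep1)), rep1, ignore_attr = TRUE)

  # a 50%-overlap pair is removed
  rep3 <- structure(data.frame(chrom = "chr1", start = 0.5e6, end = 1.5e6),
                    class = c("tad_set", "data.frame"))
  only <- structure(data.frame(chrom = "chr1", start = 0, end = 1e6),
                    class = c("tad_set", "data.frame"))
  expect_equal(nrow(merge_replicate_tads(list(only, rep3))), 0L)
})

test_that("TAD crossing statistics match their construction", {
  fm <- toy_fragment_map(100, 10000)  # 1 Mb
  tads <- structure(data.frame(chrom = "chr1", start = c(0, 5e5), end = c(5e5, 1e6)),
                    class = c("tad_set", "data.frame"))
  # all other ends within the bait's TAD
  scores <- matrix(10, 4, 1, dimnames = list(NULL, "Mon"))
  inside <- toy_interactions(fm, c(20, 20, 70, 70), c(25, 30, 75, 80), scores)
  res <- tad_crossing(inside, tads, n_perm = 50, seed = 1)
  expect_equal(res$observed, 0)

  # interactions placed uniformly at random given distances: observed near null
  set.seed(13)
  bait_idx <- sample(10:90, 40, replace = TRUE)
  oe_idx <- pmin(pmax(bait_idx + sample(c(-8:-1, 1:8), 40, replace = TRUE), 1), 100)
  rand_ints <- toy_interactions(fm, bait_idx, oe_idx,
                                matrix(10, 40, 1, dimnames = list(NULL, "Mon")))
  r2 <- tad_crossing(rand_ints, tads, n_perm = 400, seed = 2)
  expect_lt(abs(r2$observed - r2$null_mean), 3 * r2$null_sd + 0.05)
  expect_gt(r2$p, 0.01)
})

test_that("distance-matched PIR randomization preserves the binned histogram", {
  cfg <- sim_config(seed = 71, chrom_lengths = c(chr1 = 4e6), n_genes = 15)
  sim <- simulate_interactome(cfg)
  rand <- randomize_pirs_distance_matched(sim$interactions, sim$fragment_map,
                                          n_draws = 20, seed = 3)
  p <- sim$interactions$pairs
  mids <- (sim$fragment_map$start + sim$fragment_map$end) / 2
  bin_of <- function(d) floor(log2(abs(d)) / rand$bin_width)
  obs_bins <- bin_of(p$dist[rand$rows])
  bait_mid <- (p$bait_start[rand$rows] + p$bait_end[rand$rows]) / 2
  widened <- 0
  for (k in seq_len(ncol(rand$draws))) {
    d_rand <- mids[rand$draws[, k]] - bait_mid
    same <- bin_of(d_rand) == obs_bins
    widened <- widened + sum(!same)
    expect_gte(mean(same), 0.95)  # occasional single-step widening allowed
  }
  # randomized fragments never reuse observed PIR fragments
  expect_false(any(rand$draws %in% unique(p$oe_id)))
  expect_equal(nrow(rand$draws), sum(!is.na(p$dist)))
})

test_that("feature enrichment z-scores separate signal from calibrated null", {
  cfg <- sim_config(seed = 81, chrom_lengths = c(chr1 = 4e6), n_genes = 15)
  sim <- simulate_interactome(cfg)
  fm <- sim$fragment_map
  rand <- randomize_pirs_distance_matched(sim$interactions, fm,
                                          n_draws = 100, seed = 4)
  pir_ids <- unique(sim$interactions$pairs$oe_id[rand$rows])
  # features covering the PIRs (padded so random neighbours occasionally
  # overlap and the null has positive variance): strong positive z
  pir_feats <- data.frame(chrom = fm$chrom[pir_ids],
                          start = pmax(fm$start[pir_ids] - 4000, 0),
                          end = fm$end[pir_ids] + 4000)
  strong <- feature_enrichment(sim$interactions, pir_feats, rand)
  expect_gt(strong$z, 5)
  expect_equal(strong$observed, length(pir_ids))

  # no features at all
  none <- feature_enrichment(sim$interactions,
                             data.frame(chrom = character(0), start = numeric(0),
                                        end = numeric(0)), rand)
  expect_equal(none$fold, NA_real_)
  expect_equal(none$observed, 0)
})

test_that("overdispersion adjustment calibrates and resists row duplication", {
  # exactly independent one-row baits (raw chi-square 0): the bootstrap
  # statistics follow a central 1-df chi-square, so their sd is near sqrt(2)
  # and the adjustment factor near 1
  n <- 2000
  exact <- data.frame(bait = seq_len(n),
                      f1 = rep(c(TRUE, FALSE), each = n / 2),
                      f2 = rep(c(TRUE, FALSE, TRUE, FALSE), each = n / 4))
  res0 <- overdispersed_chisq(exact, n_boot = 1000, seed = 5)
  expect_lt(res0$chisq_raw, 1e-9)
  expect_lt(abs(res0$adjustment - 1), 0.1)

  # duplicating every bait's rows scales the raw statistic but not the
  # adjusted one
  set.seed(14)
  units <- data.frame(bait = seq_len(n),
                      f1 = runif(n) < 0.5, f2 = runif(n) < 0.5)
  res <- overdispersed_chisq(units, n_boot = 1000, seed = 5)
  dup <- units[rep(seq_len(n), each = 4), ]
  res4 <- overdispersed_chisq(dup, n_boot = 1000, seed = 5)
  expect_equal(res4$chisq_raw, 4 * res$chisq_raw, tolerance = 1e-9)
  expect_lt(abs(res4$chisq_adjusted / res$chisq_adjusted - 1), 0.15)

  # identical row proportions: vanishing statistic
  flat <- data.frame(bait = 1:400,
                     f1 = rep(c(TRUE, FALSE), 200),
                     f2 = rep(c(TRUE, TRUE, FALSE, FALSE), 100))
  resf <- overdispersed_chisq(flat, n_boot = 200, seed = 6)
  expect_lt(resf$chisq_raw, 1e-9)
  expect_gt(resf$p, 0.99)
})

test_that("activity coupling analysis reflects the planted coupling", {
  cfg <- sim_config(seed = 91, chrom_lengths = c(chr1 = 4e6), n_genes = 25,
                    coupling = 1)
  sim <- simulate_interactome(cfg)
  res <- activity_coupling_table(sim$interactions, sim$reg_states,
                                 mode = "enhancer_interaction",
                                 n_boot = 200, seed = 7)
  expect_gt(res$ratio[1, 1], 1)   # active enhancer & interaction present
  expect_lt(res$p, 0.01)
})
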