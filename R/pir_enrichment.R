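#' Distance-matched randomization of promoter-interacting regions
#'
#' Each draw reassigns every cis PIR to a random non-PIR fragment whose
#' bait distance falls in the same bin (log2-spaced bins of width 0.25 by
#' default), preserving the binned distance distribution and the set size
#' of the observed PIRs exactly. Trans PIRs are excluded and counted. If a
#' bin holds no candidate fragment, it is widened once by one bin on each
#' side; an empty widened bin is an error.
#'
#' @param ints an [interaction_set()].
#' @param frag_map a [fragment_map()].
#' @param n_draws number of randomized sets (default 100).
#' @param seed seed.
#' @param bin_width width of the log2 distance bins.
#' @return object of class `pir_randomization`: a matrix of fragment ids
#'   (rows = cis interactions, columns = draws) plus bookkeeping.
#' @export
randomize_pirs_distance_matched <- function(ints, frag_map, n_draws = 100, seed,
                                            bin_width = 0.25) {
  p <- ints$pairs
  cis <- !is.na(p$dist)
  n_trans <- sum(!cis)
  rows <- which(cis)
  pir_ids <- unique(p$oe_id)
  mids <- fragment_mid(frag_map)
  mc <- norm_chrom(frag_map$chrom)

  draws <- matrix(NA_integer_, length(rows), n_draws)
  withr::with_seed(seed, {
    for (k in seq_along(rows)) {
      r <- rows[k]
      bait_mid <- (p$bait_start[r] + p$bait_end[r]) / 2
      d <- abs(p$dist[r])
      b <- floor(log2(d) / bin_width)
      ci <- which(mc == norm_chrom(p$bait_chr[r]))
      cand_in_band <- function(lo, hi) {
        sel <- ci[(mids[ci] - bait_mid >= lo & mids[ci] - bait_mid < hi) |
                    (bait_mid - mids[ci] > lo & bait_mid - mids[ci] <= hi)]
        setdiff(frag_map$frag_id[sel], c(pir_ids, p$bait_id[r]))
      }
      cand <- cand_in_band(2^(bin_width * b), 2^(bin_width * (b + 1)))
      if (length(cand) == 0L) {
        cand <- cand_in_band(2^(bin_width * (b - 1)), 2^(bin_width * (b + 2)))
      }
      if (length(cand) == 0L) {
        stop_format("no candidate fragment for distance bin around %g bp", d)
      }
      draws[k, ] <- cand[sample.int(length(cand), n_draws, replace = TRUE)]
    }
  })
  structure(
    list(draws = draws, rows = rows, n_trans_excluded = n_trans,
         bin_width = bin_width, frag_map = frag_map),
    class = "pir_randomization"
  )
}

#' @export
print.pir_randomization <- function(x, ...) {
  cat(sprintf(
    "PIR randomization: %d cis PIRs x %d draws (%d trans PIRs excluded)\n",
    nrow(x$draws), ncol(x$draws), x$n_trans_excluded
  ))
  invisible(x)
}

#' Feature enrichment at PIRs against distance-matched random regions
#'
#' Counts PIR fragments overlapping at least one feature and compares with
#' the randomized draws: `fold = observed / mean(random)` and
#' `z = (observed - mean(random)) / sd(random)`.
#'
#' @param ints an [interaction_set()] (the observed PIRs are its cis other
#'   ends).
#' @param features data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param rand a `pir_randomization` for the same interaction set.
#' @param observed_frags optional fragment ids to score in place of the
#'   interaction set's own other ends (used for null calibration, where the
#'   "observed" set is itself a distance-matched draw).
#' @return data.frame with `observed`, `rand_mean`, `rand_sd`, `fold`, `z`.
#' @export
feature_enrichment <- function(ints, features, rand, observed_frags = NULL) {
  fm <- rand$frag_map
  count_frags <- function(frag_ids) {
    u <- unique(frag_ids)
    sum(overlaps_any(fm$chrom[u], fm$start[u], fm$end[u],
                     features$chrom, features$start, features$end))
  }
  p <- ints$pairs
  obs <- count_frags(observed_frags %||% p$oe_id[rand$rows])
  per_draw <- apply(rand$draws, 2, count_frags)
  m <- mean(per_draw); s <- stats::sd(per_draw)
  data.frame(
    observed = obs, rand_mean = m, rand_sd = s,
    fold = if (m > 0) obs / m else NA_real_,
    z = if (s > 0) (obs - m) / s else NA_real_
  )
}

#' Overdispersion-adjusted chi-square test on bait-grouped records
#'
#' Builds the 2x2 contingency table from binary unit records, computes the
#' Pearson chi-square, and adjusts for overdispersion arising from
#' correlated observations sharing a bait: baited fragments are resampled
#' with replacement (block bootstrap), the chi-square statistic is
#' recomputed per resample, and the observed statistic is scaled by
#' `sqrt(2)` divided by the standard deviation of the bootstrap statistics.
#' The p-value is the upper tail of a 1-df chi-square at the adjusted
#' statistic.
#'
#' @param units data.frame with logical columns `f1`, `f2` and a `bait`
#'   grouping column.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed seed.
#' @param labels optional `list(f1 = c(...), f2 = c(...))` dimension names.
#' @return list of class `contingency_result`: observed table, expected
#'   counts, observed/expected ratios, raw and adjusted chi-square,
#'   bootstrap sd and p-value.
#' @export
overdispersed_chisq <- function(units, n_boot = 1000, seed, labels = NULL) {
  tab4 <- function(f1, f2) {
    c(sum(f1 & f2), sum(!f1 & f2), sum(f1 & !f2), sum(!f1 & !f2))
  }
  v <- tab4(units$f1, units$f2)
  raw <- chisq_2x2(v)

  ub <- unique(units$bait)
  per_bait <- t(vapply(ub, function(b) {
    i <- units$bait == b
    tab4(units$f1[i], units$f2[i])
  }, numeric(4)))
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(k) {
      chisq_2x2(colSums(per_bait[sample.int(length(ub), replace = TRUE), , drop = FALSE]))
    }, numeric(1))
  })
  sd_boot <- stats::sd(boot)
  adj <- raw * sqrt(2) / sd_boot
  tab <- matrix(v, 2, 2,
                dimnames = labels %||% list(f1 = c("TRUE", "FALSE"),
                                            f2 = c("TRUE", "FALSE")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  structure(
    list(table = tab, expected = expected, ratio = tab / expected,
         chisq_raw = raw, sd_boot = sd_boot, chisq_adjusted = adj,
         adjustment = sqrt(2) / sd_boot,
         p = stats::pchisq(adj, df = 1, lower.tail = FALSE),
         n_boot = n_boot),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("Overdispersion-adjusted chi-square test\n")
  print(x$table)
  cat(sprintf("raw chi2 = %.3f, adjusted = %.3f (x %.3f), p = %.4g\n",
              x$chisq_raw, x$chisq_adjusted, x$adjustment, x$p))
  invisible(x)
}

# Per-cell-type "active" call for bait fragments: overlap with at least one
# promoter-class feature in the active state.
bait_activity_matrix <- function(ints, reg_states, cell_types) {
  feat <- reg_states[reg_states$feature_class == "promoter", , drop = FALSE]
  out <- matrix(FALSE, nrow(ints$pairs), length(cell_types),
                dimnames = list(NULL, cell_types))
  for (ct in cell_types) {
    act <- feat[feat[[ct]] == "active", , drop = FALSE]
    out[, ct] <- overlaps_any(
      ints$pairs$bait_chr, ints$pairs$bait_start, ints$pairs$bait_end,
      act$chrom, act$start, act$end
    )
  }
  out
}

#' Activity-coupling contingency analysis
#'
#' Builds the unit records for the two enhancer-promoter coupling analyses
#' and runs the overdispersion-adjusted chi-square test. The non-active
#' category pools the poised, Polycomb-repressed and inactive states.
#'
#' Modes:
#' * `"promoter_enhancer"` - one record per (interaction, cell type) pair
#'   with a high-confidence interaction, classifying bait promoter activity
#'   against other-end enhancer activity.
#' * `"enhancer_interaction"` - one record per (interaction, cell type) pair
#'   for interactions that are high-confidence in at least one cell type,
#'   classifying enhancer activity against interaction presence in that
#'   cell type.
#'
#' @param ints an [interaction_set()].
#' @param reg_states a `regulatory_states` table.
#' @param mode which 2x2 analysis to run.
#' @param score_threshold high-confidence CHiCAGO threshold.
#' @param n_boot,seed passed to [overdispersed_chisq()].
#' @return a `contingency_result`.
#' @export
activity_coupling_table <- function(ints, reg_states,
                                    mode = c("promoter_enhancer", "enhancer_interaction"),
                                    score_threshold = 5, n_boot = 1000, seed) {
  mode <- match.arg(mode)
  ct <- ints$cell_types
  enh_active <- oe_activity_matrix(ints, reg_states, ct,
                                   classes = c("proximal_enhancer", "distal_enhancer"))
  hc <- ints$scores >= score_threshold
  if (mode == "promoter_enhancer") {
    prom_active <- bait_activity_matrix(ints, reg_states, ct)
    sel <- which(hc, arr.ind = TRUE)
    units <- data.frame(
      bait = ints$pairs$bait_id[sel[, 1]],
      f1 = prom_active[sel], f2 = enh_active[sel]
    )
    labels <- list(promoter = c("active", "non-active"),
                   enhancer = c("active", "non-active"))
  } else {
    rows <- which(apply(hc, 1, any))
    sel <- cbind(rep(rows, length(ct)), rep(seq_along(ct), each = length(rows)))
    units <- data.frame(
      bait = ints$pairs$bait_id[sel[, 1]],
      f1 = enh_active[sel], f2 = hc[sel]
    )
    labels <- list(enhancer = c("active", "non-active"),
                   interaction = c("present", "absent"))
  }
  overdispersed_chisq(units, n_boot = n_boot, seed = seed, labels = labels)
}
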