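#' Directionality index from binned contact counts
#'
#' For each sliding window (25 kb wide, stepped every matrix bin) the
#' upstream and downstream contact sums A and B within a 1 Mb flank give the
#' directionality index `sign(B - A) * ((A - E)^2/E + (B - E)^2/E)` with
#' `E = (A + B)/2`; positive values indicate downstream contact bias. The
#' raw track is smoothed with a +/- 25 kb running mean and standardized to a
#' genome-wide z-score.
#'
#' @param contacts square symmetric matrix of contact counts for one
#'   chromosome, binned at `bin_bp`.
#' @param bin_bp matrix bin size in bp (the sliding step; default 5000).
#' @param window_bp width of the central window (default 25000).
#' @param flank_bp extent of the up/downstream flanks (default 1e6).
#' @param smooth_bp half-width of the smoothing window (default 25000).
#' @param chrom chromosome label for the output track.
#' @return data.frame of class `di_track` with bin midpoints, raw `di`,
#'   `smooth` and standardized `z`.
#' @export
compute_di <- function(contacts, bin_bp = 5000, window_bp = 25000,
                       flank_bp = 1e6, smooth_bp = 25000, chrom = "chr1") {
  M <- as.matrix(contacts)
  n <- nrow(M)
  hw <- floor(window_bp / bin_bp / 2)
  fl <- floor(flank_bp / bin_bp)
  di <- numeric(n)
  for (t in seq_len(n)) {
    W <- max(1L, t - hw):min(n, t + hw)
    # truncate the flanks symmetrically near the track ends, so that a
    # symmetric contact matrix scores zero everywhere
    fl_eff <- min(fl, min(W) - 1L, n - max(W))
    if (fl_eff < 1L) next
    up <- (min(W) - fl_eff):(min(W) - 1L)
    down <- (max(W) + 1L):(max(W) + fl_eff)
    A <- sum(M[W, up])
    B <- sum(M[W, down])
    E <- (A + B) / 2
    di[t] <- if (E == 0) 0 else sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
  }
  k <- 2L * floor(smooth_bp / bin_bp) + 1L
  sm <- stats::filter(di, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  # shrink the running mean at the track ends instead of dropping them
  for (t in which(is.na(sm))) {
    w <- max(1L, t - (k %/% 2L)):min(n, t + (k %/% 2L))
    sm[t] <- mean(di[w])
  }
  z <- if (stats::sd(sm) > 0) (sm - mean(sm)) / stats::sd(sm) else sm * 0
  out <- data.frame(
    chrom = chrom, mid = (seq_len(n) - 0.5) * bin_bp,
    di = di, smooth = sm, z = z
  )
  attr(out, "bin_bp") <- bin_bp
  class(out) <- c("di_track", "data.frame")
  out
}

# Indices of strict local extrema of a numeric series.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  up <- d > 0; down <- d < 0
  list(
    max = which(up[-length(up)] & down[-1L]) + 1L,
    min = which(down[-length(down)] & up[-1L]) + 1L
  )
}

#' Call TAD boundaries from a directionality-index track
#'
#' A boundary is placed between each consecutive pair of a qualifying
#' negative local extremum followed by a qualifying positive local extremum
#' of the smoothed directionality index (upstream bias giving way to
#' downstream bias), where qualifying means the standardized track exceeds
#' `z_threshold` in magnitude at the extremum. The boundary coordinate is
#' the sign change of the smoothed track between the two extrema. Domains
#' are the intervals between consecutive boundaries, including the
#' chromosome-end segments.
#'
#' @param di a `di_track` from [compute_di()].
#' @param z_threshold minimum |z| at a qualifying extremum (default 0.5).
#' @return data.frame of class `tad_set` (`chrom`, `start`, `end`) with the
#'   boundary positions in `attr(, "boundaries")`.
#' @export
call_tads <- function(di, z_threshold = 0.5) {
  ex <- local_extrema(di$smooth)
  neg <- ex$min[di$z[ex$min] < -z_threshold & di$smooth[ex$min] < 0]
  pos <- ex$max[di$z[ex$max] > z_threshold & di$smooth[ex$max] > 0]
  events <- rbind(
    data.frame(idx = neg, kind = rep("neg", length(neg))),
    data.frame(idx = pos, kind = rep("pos", length(pos)))
  )
  events <- events[order(events$idx), , drop = FALSE]
  boundaries <- numeric(0)
  if (nrow(events) >= 2L) {
    for (k in seq_len(nrow(events) - 1L)) {
      if (events$kind[k] == "neg" && events$kind[k + 1L] == "pos") {
        i0 <- events$idx[k]; i1 <- events$idx[k + 1L]
        cross <- which(di$smooth[i0:i1] >= 0)[1]
        b <- if (is.na(cross)) (i0 + i1) / 2 else i0 + cross - 1L
        boundaries <- c(boundaries, di$mid[floor(b)])
      }
    }
  }
  bin_bp <- attr(di, "bin_bp") %||% stats::median(diff(di$mid))
  lim <- c(0, max(di$mid) + bin_bp / 2)
  edges <- c(lim[1], boundaries, lim[2])
  out <- data.frame(
    chrom = di$chrom[1], start = edges[-length(edges)], end = edges[-1L]
  )
  attr(out, "boundaries") <- boundaries
  class(out) <- c("tad_set", "data.frame")
  out
}

#' Merge replicate TAD calls
#'
#' Replicate TADs are matched by reciprocal overlap; matched domains (at
#' least `min_overlap` of both lengths) are merged by averaging their
#' boundary positions, and unmatched or poorly overlapping domains are
#' dropped. Sets from more than two replicates are folded pairwise.
#'
#' @param tad_sets list of `tad_set` data.frames.
#' @param min_overlap reciprocal overlap fraction required (default 0.75).
#' @return a merged `tad_set`.
#' @export
merge_replicate_tads <- function(tad_sets, min_overlap = 0.75) {
  merge2 <- function(a, b) {
    rows <- list()
    for (i in seq_len(nrow(a))) {
      same <- which(norm_chrom(b$chrom) == norm_chrom(a$chrom[i]))
      if (length(same) == 0L) next
      ov <- pmin(b$end[same], a$end[i]) - pmax(b$start[same], a$start[i])
      j <- same[which.max(ov)]
      o <- max(ov)
      if (o >= min_overlap * (a$end[i] - a$start[i]) &&
          o >= min_overlap * (b$end[j] - b$start[j])) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = a$chrom[i],
          start = (a$start[i] + b$start[j]) / 2,
          end = (a$end[i] + b$end[j]) / 2
        )
      }
    }
    out <- if (length(rows) > 0L) do.call(rbind, rows) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    class(out) <- c("tad_set", "data.frame")
    out
  }
  Reduce(merge2, tad_sets)
}

#' TAD boundary-crossing statistics for promoter interactions
#'
#' High-confidence cis interactions whose bait lies inside a TAD are
#' classified as within-TAD or boundary-crossing by whether the other-end
#' midpoint falls outside the bait's TAD. The null expectation is obtained
#' by reshuffling the (left flank, right flank) bait-to-boundary distance
#' pairs jointly across baits and re-classifying each interaction by its
#' signed distance, preserving interaction structure and bait positioning
#' within TADs.
#'
#' @param ints an [interaction_set()].
#' @param tads a `tad_set`.
#' @param score_threshold high-confidence CHiCAGO threshold.
#' @param n_perm permutations (default 1000).
#' @param seed seed.
#' @return list of class `tad_crossing` with the observed crossing
#'   proportion, per-bait fractions, null mean/sd and an empirical one-sided
#'   p-value for depletion of crossing.
#' @export
tad_crossing <- function(ints, tads, score_threshold = 5, n_perm = 1000, seed) {
  p <- ints$pairs
  hc <- apply(ints$scores >= score_threshold, 1, any) & !is.na(p$dist)
  bait_mid <- (p$bait_start + p$bait_end) / 2
  tc <- norm_chrom(tads$chrom)
  tad_of <- rep(NA_integer_, nrow(p))
  for (ch in unique(norm_chrom(p$bait_chr))) {
    ti <- which(tc == ch)
    if (length(ti) == 0L) next
    ri <- which(norm_chrom(p$bait_chr) == ch)
    k <- findInterval(bait_mid[ri], tads$start[ti])
    ok <- k >= 1L & bait_mid[ri] < tads$end[ti][pmax(k, 1L)]
    tad_of[ri[ok]] <- ti[k[ok]]
  }
  use <- hc & !is.na(tad_of)
  dl <- bait_mid[use] - tads$start[tad_of[use]]
  dr <- tads$end[tad_of[use]] - bait_mid[use]
  d <- p$dist[use]
  bait <- p$bait_id[use]
  crossing <- d < -dl | d > dr
  obs <- mean(crossing)
  per_bait <- tapply(crossing, bait, mean)

  # permute flank-distance pairs across baits, jointly
  ub <- unique(bait)
  bait_dl <- dl[match(ub, bait)]; bait_dr <- dr[match(ub, bait)]
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample.int(length(ub))
      dl2 <- bait_dl[perm][match(bait, ub)]
      dr2 <- bait_dr[perm][match(bait, ub)]
      mean(d < -dl2 | d > dr2)
    }, numeric(1))
  })
  structure(
    list(observed = obs, per_bait = per_bait, null_mean = mean(null),
         null_sd = stats::sd(null), null = null,
         p = (1 + sum(null <= obs)) / (1 + n_perm),
         n_interactions = sum(use), n_excluded_baits = sum(hc) - sum(use)),
    class = "tad_crossing"
  )
}

#' @export
print.tad_crossing <- function(x, ...) {
  cat(sprintf(
    "TAD boundary crossing: observed %.3f vs null %.3f +/- %.3f (p = %.4g, n = %d interactions)\n",
    x$observed, x$null_mean, x$null_sd, x$p, x$n_interactions
  ))
  invisible(x)
}
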