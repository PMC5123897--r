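#' Build PIR blocks for the blockshifter test
#'
#' Fragments found in both the test and control PIR sets, or overlapping no
#' GWAS signal, are discarded. The remaining labeled fragments are grouped
#' into runs ("blocks") in which consecutive members are separated by at
#' most one non-PIR fragment on the same chromosome; each block is tagged
#' mixed (both labels present) or unmixed, and the per-fragment count and
#' sum of overlapping posterior probabilities are cached.
#'
#' @param test_frags,control_frags fragment ids of the test and control PIR
#'   sets.
#' @param frag_map a [fragment_map()].
#' @param posteriors data.frame with `chrom`, `pos`, `ppi` (SNP-level).
#' @return list of class `pir_blocks`; each element has `frag_id`, `label`,
#'   `mass`, `count` and `kind`.
#' @export
build_pir_blocks <- function(test_frags, control_frags, frag_map, posteriors) {
  both <- intersect(test_frags, control_frags)
  test_frags <- setdiff(test_frags, both)
  control_frags <- setdiff(control_frags, both)
  ids <- sort(unique(c(test_frags, control_frags)))
  if (length(ids) == 0L) stop_format("no labeled PIR fragments remain")

  snp_frag <- locate_fragment(frag_map, posteriors$chrom, posteriors$pos)
  mass <- tapply(posteriors$ppi, snp_frag, sum)
  count <- tapply(posteriors$ppi, snp_frag, length)
  frag_mass <- function(id) {
    m <- mass[as.character(id)]
    ifelse(is.na(m), 0, m)
  }
  frag_count <- function(id) {
    n <- count[as.character(id)]
    ifelse(is.na(n), 0L, as.integer(n))
  }
  keep <- frag_count(ids) > 0L
  ids <- ids[keep]
  if (length(ids) == 0L) stop_format("no PIR fragment overlaps a GWAS signal")

  chrom <- frag_map$chrom[ids]
  run_break <- c(TRUE, diff(ids) > 2L | chrom[-1L] != chrom[-length(chrom)])
  run_id <- cumsum(run_break)
  blocks <- lapply(split(seq_along(ids), run_id), function(i) {
    fid <- ids[i]
    label <- ifelse(fid %in% test_frags, "test", "control")
    list(
      frag_id = fid, label = label,
      mass = unname(frag_mass(fid)), count = unname(frag_count(fid)),
      kind = if (length(unique(label)) > 1L) "mixed" else "unmixed"
    )
  })
  names(blocks) <- NULL
  structure(blocks, class = "pir_blocks",
            n_discarded_shared = length(both))
}

#' @export
print.pir_blocks <- function(x, ...) {
  kinds <- vapply(x, `[[`, character(1), "kind")
  cat(sprintf("PIR blocks: %d blocks (%d mixed, %d unmixed), %d fragments\n",
              length(x), sum(kinds == "mixed"), sum(kinds == "unmixed"),
              sum(vapply(x, function(b) length(b$frag_id), integer(1)))))
  invisible(x)
}

#' Blockshifter enrichment statistic
#'
#' The difference in mean per-fragment posterior mass between test and
#' control fragments.
#'
#' @param blocks a `pir_blocks` list.
#' @return numeric delta.
#' @export
delta_stat <- function(blocks) {
  label <- unlist(lapply(blocks, `[[`, "label"))
  mass <- unlist(lapply(blocks, `[[`, "mass"))
  if (!any(label == "test") || !any(label == "control")) {
    stop_format("delta statistic needs both test and control fragments")
  }
  mean(mass[label == "test"]) - mean(mass[label == "control"])
}

# Internal: per-block summaries used by the permutation scheme.
blocks_summaries <- function(blocks) {
  kinds <- vapply(blocks, `[[`, character(1), "kind")
  unmixed <- which(kinds == "unmixed")
  mixed <- which(kinds == "mixed")
  list(
    unmixed = unmixed, mixed = mixed,
    u_mass = vapply(unmixed, function(i) sum(blocks[[i]]$mass), numeric(1)),
    u_n = vapply(unmixed, function(i) length(blocks[[i]]$frag_id), numeric(1)),
    u_lab = vapply(unmixed, function(i) blocks[[i]]$label[1], character(1)),
    # per mixed block, test mass/count under every rotation offset
    m_rot = lapply(mixed, function(i) {
      b <- blocks[[i]]
      m <- length(b$frag_id)
      is_test <- b$label == "test"
      rot <- vapply(seq_len(m) - 1L, function(r) {
        lab <- is_test[((seq_len(m) - 1L + r) %% m) + 1L]
        c(sum(b$mass[lab]), sum(lab), sum(b$mass[!lab]), sum(!lab))
      }, numeric(4))
      t(rot)
    })
  )
}

#' Permutation null for the blockshifter statistic
#'
#' Unmixed blocks have their whole-block labels re-dealt at random,
#' preserving the observed numbers of test and control unmixed blocks;
#' mixed blocks are conceptually circularized and their label sequence
#' rotated by a uniformly random offset (the identity rotation allowed
#' unless `exclude_identity`). The delta statistic is recomputed per
#' permutation.
#'
#' @param blocks a `pir_blocks` list.
#' @param n_perm number of permutations.
#' @param seed seed.
#' @param exclude_identity disallow the identity rotation for mixed blocks.
#' @return numeric vector of null deltas.
#' @export
permute_blocks <- function(blocks, n_perm, seed, exclude_identity = FALSE) {
  if (n_perm < 100) warning("fewer than 100 permutations; null sd will be noisy")
  s <- blocks_summaries(blocks)
  n_u <- length(s$unmixed)
  withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      t_mass <- 0; t_n <- 0; c_mass <- 0; c_n <- 0
      if (n_u > 0L) {
        # permute the observed label multiset across unmixed blocks; this
        # preserves the block label counts and is label-symmetric
        is_t <- (s$u_lab == "test")[sample.int(n_u)]
        t_mass <- sum(s$u_mass[is_t]); t_n <- sum(s$u_n[is_t])
        c_mass <- sum(s$u_mass[!is_t]); c_n <- sum(s$u_n[!is_t])
      }
      for (rot in s$m_rot) {
        m <- nrow(rot)
        offs <- if (exclude_identity && m > 1L) 1L + sample.int(m - 1L, 1) else sample.int(m, 1)
        t_mass <- t_mass + rot[offs, 1]; t_n <- t_n + rot[offs, 2]
        c_mass <- c_mass + rot[offs, 3]; c_n <- c_n + rot[offs, 4]
      }
      t_mass / t_n - c_mass / c_n
    }, numeric(1))
  })
}

#' Blockshifter tissue-set enrichment test
#'
#' Competitive test of GWAS posterior-mass enrichment at PIRs of a test
#' tissue set against a control set, with a permutation null that respects
#' spatial correlation of PIRs by permuting whole blocks (label re-deal for
#' unmixed blocks, circular rotation for mixed blocks). The result is an
#' empirical Z-score `(delta - mean(delta_null)) / sd(delta_null)`; a
#' degenerate null (zero sd) is reported as Z = 0 with a flag.
#'
#' @param test_frags,control_frags fragment ids of the two PIR sets.
#' @param frag_map a [fragment_map()].
#' @param posteriors data.frame with `chrom`, `pos`, `ppi`.
#' @param n_perm permutations (default 10000).
#' @param seed seed.
#' @param exclude_identity passed to [permute_blocks()].
#' @return list of class `blockshifter_result`.
#' @export
blockshifter_z <- function(test_frags, control_frags, frag_map, posteriors,
                           n_perm = 10000, seed, exclude_identity = FALSE) {
  blocks <- build_pir_blocks(test_frags, control_frags, frag_map, posteriors)
  delta <- delta_stat(blocks)
  null <- permute_blocks(blocks, n_perm, seed, exclude_identity)
  s <- stats::sd(null)
  degenerate <- !is.finite(s) || s == 0
  z <- if (degenerate) 0 else (delta - mean(null)) / s
  label <- unlist(lapply(blocks, `[[`, "label"))
  structure(
    list(delta = delta, delta_null = null, z = z, degenerate = degenerate,
         n_perm = n_perm, n_test = sum(label == "test"),
         n_control = sum(label == "control"), blocks = blocks),
    class = "blockshifter_result"
  )
}

#' @export
print.blockshifter_result <- function(x, ...) {
  cat(sprintf(
    "Blockshifter: delta = %.4g, Z = %.3f (%d test / %d control fragments, %d permutations)%s\n",
    x$delta, x$z, x$n_test, x$n_control, x$n_perm,
    if (x$degenerate) " [degenerate null]" else ""
  ))
  invisible(x)
}
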