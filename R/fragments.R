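#' Restriction fragment maps
#'
#' A fragment map describes the genome-wide tiling of a restriction digest
#' (HindIII in blood-cell PCHi-C): non-overlapping fragments that cover each
#' chromosome without gaps, numbered by a single integer ordinal along the
#' genome. Coordinates are 0-based half-open throughout the package.
#'
#' @param chrom chromosome name per fragment.
#' @param start,end 0-based half-open fragment interval.
#' @param is_bait logical; whether the fragment contains a captured promoter.
#' @return A `data.frame` of class `fragment_map` with columns `chrom`,
#'   `start`, `end`, `frag_id` (ordinal along the sorted genome) and
#'   `is_bait`.
#' @export
fragment_map <- function(chrom, start, end, is_bait = FALSE) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    is_bait = rep_len(as.logical(is_bait), length(chrom)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  if (any(df$start < 0) || any(df$start >= df$end)) {
    stop_format("fragment intervals must satisfy 0 <= start < end")
  }
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 1L && any(sub$start[-1L] != sub$end[-nrow(sub)])) {
      stop_format("fragments must tile chromosome %s without gaps or overlaps", ch)
    }
  }
  df$frag_id <- seq_len(nrow(df))
  rownames(df) <- NULL
  class(df) <- c("fragment_map", "data.frame")
  df[, c("chrom", "start", "end", "frag_id", "is_bait")]
}

#' Locate the fragment covering each genomic position
#'
#' Fragments tile the genome, so every in-range position is covered by exactly
#' one fragment.
#'
#' @param map a [fragment_map()].
#' @param chrom,pos query positions (0-based).
#' @return Integer vector of `frag_id`s; `NA` for positions outside the map.
#' @export
locate_fragment <- function(map, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  qc <- norm_chrom(rep_len(chrom, length(pos)))
  mc <- norm_chrom(map$chrom)
  for (ch in unique(qc)) {
    mi <- which(mc == ch)
    if (length(mi) == 0L) next
    qi <- which(qc == ch)
    k <- findInterval(pos[qi], map$start[mi])
    ok <- k >= 1L & pos[qi] < map$end[mi][pmax(k, 1L)]
    out[qi[ok]] <- map$frag_id[mi][k[ok]]
  }
  out
}

fragment_mid <- function(map, frag_id = NULL) {
  if (is.null(frag_id)) (map$start + map$end) / 2
  else (map$start[frag_id] + map$end[frag_id]) / 2
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf(
    "Fragment map: %d fragments on %d chromosome(s), %d bait(s)\n",
    nrow(x), length(unique(x$chrom)), sum(x$is_bait)
  ))
  invisible(x)
}
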