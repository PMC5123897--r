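# Internal helpers shared across modules.

# Chromosome names are compared after stripping any "chr" prefix, so "6" and
# "chr6" refer to the same chromosome.
norm_chrom <- function(x) sub("^chr", "", as.character(x))

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seeds derived from a master seed must stay within R's 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * offset) %% .Machine$integer.max)
}

# Pearson chi-square statistic for a 2x2 table given as c(a, b, c, d)
# (column-major). Returns 0 when a margin is empty.
chisq_2x2 <- function(v) {
  v <- as.numeric(v)  # avoid integer overflow in the margin product
  a <- v[1L]; b <- v[2L]; c <- v[3L]; d <- v[4L]
  n <- a + b + c + d
  m <- (a + b) * (c + d) * (a + c) * (b + d)
  if (m == 0 || n == 0) return(0)
  n * (a * d - b * c)^2 / m
}

# Overlap test between 0-based half-open intervals: for each query, TRUE if it
# overlaps any subject interval on the same chromosome.
overlaps_any <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  out <- logical(length(q_chrom))
  if (length(s_chrom) == 0L || length(q_chrom) == 0L) return(out)
  qc <- norm_chrom(q_chrom); sc <- norm_chrom(s_chrom)
  for (ch in unique(qc)) {
    qi <- which(qc == ch)
    si <- which(sc == ch)
    if (length(si) == 0L) next
    hits <- IRanges::overlapsAny(
      IRanges::IRanges(start = q_start[qi] + 1L, end = q_end[qi]),
      IRanges::IRanges(start = s_start[si] + 1L, end = s_end[si])
    )
    out[qi] <- hits
  }
  out
}
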