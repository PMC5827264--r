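# Ungapped plus-strand local matching between two sequences.
#
# Seed-and-extend on diagonals: shared k-mers nominate diagonals, each
# diagonal is scanned for maximal exact runs, and adjacent runs on the
# same diagonal are greedily fused across mismatches while the fused
# segment keeps the required identity. N is never a match (gap sequence
# must not align). Intended for sequences up to ~10 kb.
#
# Returns a data.frame of candidate blocks in 0-based half-open
# coordinates on both sequences; blocks from different diagonals may
# overlap — callers select among them.
ungapped_matches <- function(x, y, min_identity = 90, min_len = 20L, k = NULL,
                             x_kmers = NULL, y_index = NULL) {
  empty <- data.frame(x_start = integer(), x_end = integer(),
                      y_start = integer(), y_end = integer(),
                      length = integer(), matches = integer(),
                      pct_identity = numeric())
  nx <- nchar(x); ny <- nchar(y)
  if (nx == 0L || ny == 0L || min_len > min(nx, ny)) return(empty)
  xr <- charToRaw(toupper(x)); yr <- charToRaw(toupper(y))
  nraw <- charToRaw("N")
  if (is.null(k)) k <- max(1L, min(12L, as.integer(min_len)))

  if (is.null(y_index) && (as.double(nx) * ny <= 250000 || k == 1L)) {
    diags <- seq.int(-(nx - 1L), ny - 1L)
  } else {
    if (is.null(x_kmers)) x_kmers <- seq_kmers(x, k)
    if (is.null(y_index)) y_index <- kmer_index(y, k)
    hit <- which(x_kmers %in% names(y_index))
    if (length(hit) == 0L) return(empty)
    diags <- unique(unlist(lapply(hit, function(i)
      y_index[[x_kmers[i]]] - i), use.names = FALSE))
  }

  out <- vector("list", length(diags))
  min_frac <- min_identity / 100
  for (di in seq_along(diags)) {
    d <- diags[di]
    i0 <- max(1L, 1L - d); i1 <- min(nx, ny - d)
    if (i1 - i0 + 1L < min_len) next
    xi <- xr[i0:i1]; yi <- yr[(i0 + d):(i1 + d)]
    m <- xi == yi & xi != nraw & yi != nraw
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seg <- data.frame(start = starts[r$values], end = ends[r$values])
    if (nrow(seg) == 0L) next
    seg$matches <- seg$end - seg$start + 1L
    # fuse neighbouring exact runs across mismatch gaps under ungapped
    # local-alignment scoring (+2 match / -3 mismatch): a fusion must be
    # paid for by the weaker of the two runs, so a long run can never
    # absorb unrelated sequence just because its global identity allows it
    repeat {
      if (nrow(seg) < 2L) break
      gap <- seg$start[-1L] - seg$end[-nrow(seg)] - 1L
      shorter <- pmin(seg$matches[-1L], seg$matches[-nrow(seg)])
      # the weaker run must both pay for the gap and be long enough not
      # to be a chance match (4 bp floor)
      benefit <- ifelse(shorter >= 4L, 2L * shorter - 3L * gap, -1L)
      best <- which.max(benefit)
      if (benefit[best] <= 0L) break
      seg$end[best] <- seg$end[best + 1L]
      seg$matches[best] <- seg$matches[best] + seg$matches[best + 1L]
      seg <- seg[-(best + 1L), , drop = FALSE]
    }
    span <- seg$end - seg$start + 1L
    keep <- span >= min_len & seg$matches / span >= min_frac
    seg <- seg[keep, , drop = FALSE]
    if (nrow(seg) == 0L) next
    span <- seg$end - seg$start + 1L
    out[[di]] <- data.frame(
      x_start = i0 + seg$start - 2L, x_end = i0 + seg$end - 1L,
      y_start = i0 + d + seg$start - 2L, y_end = i0 + d + seg$end - 1L,
      length = span, matches = seg$matches,
      pct_identity = 100 * seg$matches / span)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) empty else res
}

seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  s <- seq_len(n - k + 1L)
  substring(toupper(seq), s, s + k - 1L)
}

# kmer -> integer positions (1-based) lookup table
kmer_index <- function(seq, k) {
  km <- seq_kmers(seq, k)
  split(seq_along(km), km)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
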