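# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own algorithms: coverage by
# per-base bit vectors, alignment by exhaustive run enumeration, ORFs by
# a plain codon walk.

# per-base coverage oracle: logical vector of length len
oracle_cover_bases <- function(starts, ends, len) {
  v <- logical(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) v[(starts[i] + 1L):ends[i]] <- TRUE
  }
  v
}

# maximal uncovered runs of at least min_len, from the per-base vector
oracle_uncovered <- function(cover, min_len) {
  r <- rle(!cover)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

# exhaustive enumeration of maximal exact-match runs between two strings
oracle_exact_blocks <- function(a, b, min_len = 1L) {
  av <- strsplit(toupper(a), "")[[1L]]
  bv <- strsplit(toupper(b), "")[[1L]]
  ok <- function(i, j) i >= 1L && j >= 1L && i <= length(av) &&
    j <= length(bv) && av[i] == bv[j] && av[i] != "N"
  res <- list()
  for (i in seq_along(av)) {
    for (j in seq_along(bv)) {
      if (!ok(i, j) || ok(i - 1L, j - 1L)) next  # only run starts
      l <- 0L
      while (ok(i + l, j + l)) l <- l + 1L
      if (l >= min_len)
        res[[length(res) + 1L]] <- data.frame(a_start = i - 1L, a_end = i - 1L + l,
                                              b_start = j - 1L, b_end = j - 1L + l,
                                              length = l)
    }
  }
  if (length(res) == 0L)
    return(data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      length = integer()))
  do.call(rbind, res)
}

# plain 3-frame codon walk; reports complete, 3'-partial and leading
# 5'-partial ORFs exactly as the scanner is specified to
oracle_orfs <- function(seq, min_aa = 1L) {
  stops <- c("TAA", "TAG", "TGA")
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    pos <- f + 1L
    orf_start <- NA_integer_   # nt position of current ATG
    seen_any <- FALSE          # codon seen in current segment
    seg_first <- pos           # first codon position of current segment
    while (pos + 2L <= n) {
      cod <- substr(seq, pos, pos + 2L)
      if (cod %in% stops) {
        if (!is.na(orf_start)) {
          out[[length(out) + 1L]] <- data.frame(
            frame = f, start = orf_start - 1L, end = pos - 1L,
            length_aa = (pos - orf_start) / 3L, completeness = "complete")
        } else if (seg_first == f + 1L && seen_any) {
          out[[length(out) + 1L]] <- data.frame(
            frame = f, start = seg_first - 1L, end = pos - 1L,
            length_aa = (pos - seg_first) / 3L,
            completeness = "five_prime_partial")
        }
        orf_start <- NA_integer_
        seen_any <- FALSE
        seg_first <- pos + 3L
      } else {
        seen_any <- TRUE
        if (is.na(orf_start) && cod == "ATG") orf_start <- pos
      }
      pos <- pos + 3L
    }
    if (!is.na(orf_start)) {
      out[[length(out) + 1L]] <- data.frame(
        frame = f, start = orf_start - 1L, end = pos - 1L,
        length_aa = (pos - orf_start) / 3L,
        completeness = "three_prime_partial")
    }
  }
  res <- do.call(rbind, c(out, list(data.frame(
    frame = integer(), start = integer(), end = integer(),
    length_aa = integer(), completeness = character()))))
  res[res$length_aa >= min_aa, , drop = FALSE]
}

# sort-and-pick median
oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2L == 1L) x[(n + 1L) / 2L] else (x[n / 2L] + x[n / 2L + 1L]) / 2
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

empty_hits_for_test <- function() {
  h <- mk_hits("c1", "g1", qs = 1L, qe = 10L, ss = 1L, se = 10L)
  h[0, , drop = FALSE]
}

interval_union_for_test <- function(s, e) {
  if (length(s) == 0L) return(data.frame(start = integer(), end = integer()))
  v <- oracle_cover_bases(s, e, max(e))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

setdiff_codons <- function() {
  all <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           c("A", "C", "G", "T")), 1L, paste, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# build a hits_tab row set quickly (1-based inclusive coordinates)
mk_hits <- function(query_id, subject_id, qs, qe, ss, se, identity = 100,
                    bitscore = NULL, evalue = NULL, ...) {
  n <- max(length(query_id), length(subject_id), length(qs))
  df <- data.frame(query_id = rep_len(query_id, n),
                   subject_id = rep_len(subject_id, n),
                   pct_identity = rep_len(identity, n),
                   aln_length = rep_len(qe, n) - rep_len(qs, n) + 1L,
                   mismatches = 0L, gap_open = 0L,
                   q_start = rep_len(qs, n), q_end = rep_len(qe, n),
                   s_start = rep_len(ss, n), s_end = rep_len(se, n),
                   s_strand = "+",
                   evalue = if (is.null(evalue)) 1e-50 else rep_len(evalue, n),
                   bitscore = if (is.null(bitscore))
                     2 * (rep_len(qe, n) - rep_len(qs, n) + 1L) else
                       rep_len(bitscore, n),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  class(df) <- c("hits_tab", "data.frame")
  df
}

# minimal exon-table constructor
mk_exons <- function(seqid, start, end, strand, gene_id, transcript_id,
                     source = "test") {
  data.frame(seqid = seqid, start = as.integer(start), end = as.integer(end),
             strand = strand, gene_id = gene_id,
             transcript_id = transcript_id, source = source,
             stringsAsFactors = FALSE)
}

# paired-record constructor in the read_sam_min()$pairs layout
mk_pairs <- function(name, flag1, flag2, ref1, ref2, pos1, pos2,
                     span1 = 50L, span2 = 50L) {
  data.frame(query_name = name, flag1 = as.integer(flag1),
             flag2 = as.integer(flag2), ref1 = ref1, ref2 = ref2,
             pos1 = as.integer(pos1), pos2 = as.integer(pos2),
             mapq1 = 60L, mapq2 = 60L,
             span1 = as.integer(span1), span2 = as.integer(span2),
             stringsAsFactors = FALSE)
}
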