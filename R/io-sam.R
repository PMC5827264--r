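#' Minimal SAM reader returning paired records
#'
#' Reads a text SAM file keeping only the fields the fragment counter
#' needs (FLAG, RNAME, POS, MAPQ, CIGAR) and joins mates by query name
#' and the first/second-in-pair FLAG bits. Secondary records (0x100) are
#' used only when no primary record exists for that mate; the secondary
#' bit stays visible to the caller. Records whose mate is absent from the
#' file are returned in an `orphans` table rather than silently dropped.
#' Chimeric pairs (mates on different reference sequences) are retained:
#' they are the very signal the fragmentation correction exploits.
#'
#' @param path path to a SAM text file.
#' @param default_read_len reference span to assume when a record has no
#'   CIGAR (`*`); reads here are fixed-length, so a constant is adequate.
#' @return list with elements `pairs` (data.frame: `query_name`, `flag1`,
#'   `flag2`, `ref1`, `ref2`, `pos1`, `pos2` (1-based), `mapq1`, `mapq2`,
#'   `span1`, `span2` reference spans in bp) and `orphans` (data.frame of
#'   unpaired records).
#' @export
read_sam_min <- function(path, default_read_len = 50L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(list(pairs = empty_pairs(), orphans = empty_orphans()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L))
    stop("SAM record with fewer than 11 fields at line ",
         which(lengths(fields) < 11L)[1L])
  rec <- data.frame(
    query_name = vapply(fields, `[[`, "", 1L),
    flag = as.integer(vapply(fields, `[[`, "", 2L)),
    ref = vapply(fields, `[[`, "", 3L),
    pos = as.integer(vapply(fields, `[[`, "", 4L)),
    mapq = as.integer(vapply(fields, `[[`, "", 5L)),
    cigar = vapply(fields, `[[`, "", 6L),
    stringsAsFactors = FALSE)
  if (any(bitwAnd(rec$flag, 1L) == 0L))
    stop("unpaired record (FLAG bit 0x1 unset) for read ",
         rec$query_name[bitwAnd(rec$flag, 1L) == 0L][1L])
  rec$span <- cigar_ref_span(rec$cigar, default_read_len)
  first <- bitwAnd(rec$flag, 64L) > 0L
  second <- bitwAnd(rec$flag, 128L) > 0L
  if (any(first == second))
    stop("record with invalid first/second-in-pair bits for read ",
         rec$query_name[first == second][1L])

  pick <- function(d) {  # prefer the primary record for each mate
    if (nrow(d) == 1L) return(d)
    prim <- d[bitwAnd(d$flag, 256L) == 0L, , drop = FALSE]
    if (nrow(prim) >= 1L) prim[1L, , drop = FALSE] else d[1L, , drop = FALSE]
  }
  r1 <- do.call(rbind, lapply(split(rec[first, , drop = FALSE],
                                    rec$query_name[first]), pick))
  r2 <- do.call(rbind, lapply(split(rec[second, , drop = FALSE],
                                    rec$query_name[second]), pick))
  common <- intersect(r1$query_name, r2$query_name)
  i1 <- match(common, r1$query_name)
  i2 <- match(common, r2$query_name)
  pairs <- data.frame(
    query_name = common,
    flag1 = r1$flag[i1], flag2 = r2$flag[i2],
    ref1 = r1$ref[i1], ref2 = r2$ref[i2],
    pos1 = r1$pos[i1], pos2 = r2$pos[i2],
    mapq1 = r1$mapq[i1], mapq2 = r2$mapq[i2],
    span1 = r1$span[i1], span2 = r2$span[i2],
    stringsAsFactors = FALSE)
  orphan <- rbind(r1[!r1$query_name %in% common, , drop = FALSE],
                  r2[!r2$query_name %in% common, , drop = FALSE])
  rownames(pairs) <- rownames(orphan) <- NULL
  list(pairs = pairs, orphans = orphan[, c("query_name", "flag", "ref", "pos")])
}

empty_pairs <- function() {
  data.frame(query_name = character(), flag1 = integer(), flag2 = integer(),
             ref1 = character(), ref2 = character(),
             pos1 = integer(), pos2 = integer(),
             mapq1 = integer(), mapq2 = integer(),
             span1 = integer(), span2 = integer(), stringsAsFactors = FALSE)
}

empty_orphans <- function() {
  data.frame(query_name = character(), flag = integer(),
             ref = character(), pos = integer(), stringsAsFactors = FALSE)
}

#' Reference span of a CIGAR string
#'
#' Sums the reference-consuming operations (M, D, N, =, X). Records
#' without a CIGAR (`*`) fall back to `default_len`.
#'
#' @param cigar character vector of CIGAR strings.
#' @param default_len span to use for `*`.
#' @return integer vector of spans.
#' @export
cigar_ref_span <- function(cigar, default_len = 50L) {
  vapply(cigar, function(cg) {
    if (cg == "*" || !nzchar(cg)) return(as.integer(default_len))
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1L]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    if (length(toks) == 0L) stop("unparsable CIGAR: ", cg)
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    as.integer(sum(n[op %in% c("M", "D", "N", "=", "X")]))
  }, integer(1), USE.NAMES = FALSE)
}

#' Write paired records as a minimal SAM text file
#'
#' Emits one line per mate with FLAG, RNAME, POS, MAPQ and a fully-matched
#' CIGAR of the given span; SEQ/QUAL are `*`. Enough for [read_sam_min()]
#' and the fragment counter; not a general SAM writer.
#'
#' @param pairs data.frame in the layout returned by `read_sam_min()$pairs`.
#' @param path output path.
#' @param seq_lengths optional named vector of reference lengths for
#'   `@SQ` headers.
#' @return `path`, invisibly.
#' @export
write_sam_min <- function(pairs, path, seq_lengths = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(seq_lengths))
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                          as.integer(seq_lengths)))
  line <- function(name, flag, ref, pos, mapq, span) {
    cigar <- ifelse(ref == "*", "*", sprintf("%dM", span))
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
            name, flag, ref, pos, mapq, cigar)
  }
  l1 <- line(pairs$query_name, pairs$flag1, pairs$ref1, pairs$pos1,
             pairs$mapq1, pairs$span1)
  l2 <- line(pairs$query_name, pairs$flag2, pairs$ref2, pairs$pos2,
             pairs$mapq2, pairs$span2)
  writeLines(c(hdr, as.vector(rbind(l1, l2))), path)
  invisible(path)
}
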