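#' Read a 12-column tabular pairwise-alignment hit file
#'
#' The format is the standard 12-column tabular output of pairwise local
#' aligners (query, subject, percent identity, alignment length,
#' mismatches, gap openings, query start/end, subject start/end, e-value,
#' bit score; all coordinates 1-based inclusive). Subject coordinates with
#' `s_start > s_end` encode a minus-strand subject match; they are
#' normalised to ascending order at parse time and the orientation kept in
#' an explicit `s_strand` column, so downstream interval algebra can
#' assume `start <= end`.
#'
#' @param path path to the tab-separated hit file.
#' @return data.frame of class `hits_tab` with columns `query_id`,
#'   `subject_id`, `pct_identity`, `aln_length`, `mismatches`, `gap_open`,
#'   `q_start`, `q_end`, `s_start`, `s_end` (1-based inclusive, ascending),
#'   `s_strand`, `evalue`, `bitscore`.
#' @export
read_hits_tab <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("expected 12 tab-separated columns, got ", nf[which(nf != 12L)[1L]],
         " at line ", which(nf != 12L)[1L], " of ", path)
  m <- do.call(rbind, fields)
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    pct_identity = as.numeric(m[, 3L]), aln_length = as.integer(m[, 4L]),
    mismatches = as.integer(m[, 5L]), gap_open = as.integer(m[, 6L]),
    q_start = as.integer(m[, 7L]), q_end = as.integer(m[, 8L]),
    s_start = as.integer(m[, 9L]), s_end = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE)
  normalize_hits(hits)
}

empty_hits <- function() {
  h <- data.frame(query_id = character(), subject_id = character(),
                  pct_identity = numeric(), aln_length = integer(),
                  mismatches = integer(), gap_open = integer(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  s_strand = character(),
                  evalue = numeric(), bitscore = numeric(),
                  stringsAsFactors = FALSE)
  class(h) <- c("hits_tab", "data.frame")
  h
}

# normalise subject coordinates to ascending + explicit strand, validate
normalize_hits <- function(hits) {
  if (is.null(hits$s_strand)) {
    minus <- hits$s_start > hits$s_end
    hits$s_strand <- ifelse(minus, "-", "+")
    tmp <- hits$s_start[minus]
    hits$s_start[minus] <- hits$s_end[minus]
    hits$s_end[minus] <- tmp
  }
  if (any(hits$q_start > hits$q_end)) stop("hit with q_start > q_end")
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
    stop("pct_identity outside [0, 100]")
  if (any(hits$aln_length < 1L)) stop("hit with aln_length < 1")
  hits <- hits[, c("query_id", "subject_id", "pct_identity", "aln_length",
                   "mismatches", "gap_open", "q_start", "q_end",
                   "s_start", "s_end", "s_strand", "evalue", "bitscore")]
  class(hits) <- c("hits_tab", "data.frame")
  hits
}

#' Write a hit table in 12-column tabular format
#'
#' Minus-strand subject hits are emitted with descending subject
#' coordinates, the convention [read_hits_tab()] parses back.
#'
#' @param hits a `hits_tab` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tab <- function(hits, path) {
  s1 <- ifelse(hits$s_strand == "-", hits$s_end, hits$s_start)
  s2 <- ifelse(hits$s_strand == "-", hits$s_start, hits$s_end)
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2g\t%.1f",
                   hits$query_id, hits$subject_id, hits$pct_identity,
                   hits$aln_length, hits$mismatches, hits$gap_open,
                   hits$q_start, hits$q_end, s1, s2, hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}
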