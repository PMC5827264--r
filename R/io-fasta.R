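#' Read a FASTA file
#'
#' Sequence identifiers are the first whitespace-delimited token of each
#' header. Case is preserved verbatim: the pipeline's alignment steps are
#' run without masking, so case carries no meaning and is never touched.
#'
#' @param path path to a FASTA file.
#' @return Named character vector mapping sequence id to sequence text.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) > 0L && !startsWith(trimws(first[nonblank[1L]]), ">"))
    stop("malformed FASTA header at line ", nonblank[1L], " of ", path)
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA
#'
#' @param records named character vector (id -> sequence).
#' @param path output path.
#' @param line_width bases per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  stopifnot(length(records) == 0L || !is.null(names(records)))
  x <- Biostrings::BStringSet(unname(as.character(records)))
  names(x) <- names(records)
  Biostrings::writeXStringSet(x, path, width = as.integer(line_width))
  invisible(path)
}

#' Read a FASTQ file into a paired-vector read set
#'
#' Quality strings are decoded as Phred+33 (the standard encoding of the
#' sequencer generation this pipeline targets).
#'
#' @param path path to a FASTQ file.
#' @return An object of class `fastq_reads`: a list with `id` (character),
#'   `seq` (character) and `qual` (list of integer Phred vectors).
#' @export
read_fastq <- function(path) {
  # Biostrings warns that fastq metadata columns are dropped; nothing we
  # keep lives there
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  qual <- as.list(methods::as(Biostrings::quality(x), "IntegerList"))
  fastq_reads(sub("\\s.*$", "", names(x)), as.character(x), qual)
}

#' Construct a `fastq_reads` object
#'
#' @param id,seq character vectors; `qual` list of integer Phred vectors.
#' @return `fastq_reads` object.
#' @export
fastq_reads <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  bad <- which(nchar(seq) != lengths(qual))
  if (length(bad)) stop("sequence/quality length mismatch for read ", id[bad[1L]])
  structure(list(id = as.character(id), seq = as.character(seq),
                 qual = lapply(qual, as.integer)),
            class = "fastq_reads")
}

#' @export
length.fastq_reads <- function(x) length(x$id)

#' @export
print.fastq_reads <- function(x, ...) {
  cat("<fastq_reads> ", length(x), " reads\n", sep = "")
  invisible(x)
}

# subset a fastq_reads object by index
fastq_subset <- function(x, i) {
  fastq_reads(x$id[i], x$seq[i], x$qual[i])
}

#' Write a `fastq_reads` object as FASTQ (Phred+33)
#'
#' @param reads a `fastq_reads` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "fastq_reads"))
  qs <- vapply(reads$qual, function(q) rawToChar(as.raw(q + 33L)), character(1))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(qs))
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
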