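#' Read a GTF annotation into an exon table
#'
#' Reads the Cufflinks GTF dialect (mandatory `gene_id` and `transcript_id`
#' attributes) and returns exon features as a flat table in internal
#' 0-based half-open coordinates. Only `exon` features are retained; other
#' feature types (CDS, start_codon, ...) are ignored.
#'
#' @param path path to a GTF file.
#' @return data.frame with columns `seqid`, `start`, `end` (0-based
#'   half-open), `strand`, `gene_id`, `transcript_id`, `source`, sorted by
#'   transcript then start.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) return(empty_exon_table())
  gid <- if (is.null(gr$gene_id)) rep(NA_character_, length(gr)) else
    as.character(gr$gene_id)
  tid <- if (is.null(gr$transcript_id)) rep(NA_character_, length(gr)) else
    as.character(gr$transcript_id)
  if (anyNA(gid) || anyNA(tid))
    stop("GTF exon feature missing mandatory gene_id/transcript_id attribute in ", path)
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gid,
    transcript_id = tid,
    source = as.character(gr$source),
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "*"
  df[order(df$gene_id, df$transcript_id, df$start), , drop = FALSE]
}

empty_exon_table <- function() {
  data.frame(seqid = character(), start = integer(), end = integer(),
             strand = character(), gene_id = character(),
             transcript_id = character(), source = character(),
             stringsAsFactors = FALSE)
}

#' Write an exon table as GTF
#'
#' Internal 0-based half-open coordinates are converted back to the GTF
#' 1-based inclusive convention, so `read_gtf(write_gtf(x))` is lossless.
#'
#' @param exons exon table as returned by [read_gtf()]; a missing `source`
#'   column defaults to `"dualtx"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path) {
  if (is.null(exons$source)) exons$source <- "dualtx"
  strand <- ifelse(exons$strand == "*", ".", exons$strand)
  lines <- sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    exons$seqid, exons$source, exons$start + 1L, exons$end, strand,
    exons$gene_id, exons$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Split an exon table into per-transcript models
#'
#' @param exons exon table.
#' @return named list (by transcript_id) of exon tables, exons sorted by
#'   start; an error is raised if a transcript's exons overlap or span
#'   several sequences/strands.
#' @export
split_transcripts <- function(exons) {
  out <- split(exons, exons$transcript_id)
  lapply(out, function(tx) {
    tx <- tx[order(tx$start), , drop = FALSE]
    if (length(unique(tx$seqid)) != 1L || length(unique(tx$strand)) != 1L)
      stop("transcript ", tx$transcript_id[1L], " spans several sequences or strands")
    if (nrow(tx) > 1L && any(tx$start[-1L] < tx$end[-nrow(tx)]))
      stop("transcript ", tx$transcript_id[1L], " has overlapping exons")
    rownames(tx) <- NULL
    tx
  })
}
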