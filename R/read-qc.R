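#' Median Phred quality of a read
#'
#' The statistical median of the per-base Phred scores: for an even
#' number of bases, the mean of the two central values.
#'
#' @param qual integer vector of Phred scores (one read), or a
#'   `fastq_reads` object (vectorised over reads).
#' @return numeric median (vector for `fastq_reads` input).
#' @examples
#' median_quality(c(30L, 28L, 27L, 40L, 28L))  # 28
#' median_quality(c(28L, 29L, 27L, 30L))       # 28.5
#' @export
median_quality <- function(qual) {
  if (inherits(qual, "fastq_reads"))
    return(vapply(qual$qual, median_quality, numeric(1)))
  if (length(qual) == 0L) stop("cannot take the median quality of an empty read")
  stats::median(as.numeric(qual))
}

#' Filter read pairs on median base quality
#'
#' The quality gate applied before de novo assembly: a pair is kept only
#' if **both** mates have a median Phred quality of at least `min_median`
#' (reads with a median quality strictly lower than the threshold are
#' discarded, so a median exactly at the threshold passes). The whole
#' pair is discarded when either mate fails, because only complete read
#' pairs are useful to the downstream assembler.
#'
#' @param r1,r2 `fastq_reads` objects with mates in matching order
#'   (validated by read id up to a trailing `/1` / `/2` suffix).
#' @param min_median quality threshold (default 28).
#' @return list with `kept1`, `kept2` (`fastq_reads`) and `discarded`,
#'   a data.frame logging `read_id`, both medians and which mate failed.
#' @export
filter_pairs <- function(r1, r2, min_median = 28) {
  stopifnot(inherits(r1, "fastq_reads"), inherits(r2, "fastq_reads"))
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  core <- function(id) sub("/[12]$", "", id)
  if (!all(core(r1$id) == core(r2$id)))
    stop("mates are not paired by read id")
  m1 <- median_quality(r1)
  m2 <- median_quality(r2)
  keep <- m1 >= min_median & m2 >= min_median
  failed <- ifelse(!keep,
                   ifelse(m1 < min_median & m2 < min_median, "both",
                          ifelse(m1 < min_median, "mate1", "mate2")), "")
  discarded <- data.frame(read_id = core(r1$id)[!keep],
                          median1 = m1[!keep], median2 = m2[!keep],
                          failed_mate = failed[!keep],
                          stringsAsFactors = FALSE)
  list(kept1 = fastq_subset(r1, keep), kept2 = fastq_subset(r2, keep),
       discarded = discarded)
}
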