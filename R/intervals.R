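#' Genomic interval tables
#'
#' Throughout the package intervals are 0-based half-open `[start, end)`.
#' All external formats (GTF, SAM, tabular alignment hits) are 1-based
#' inclusive; conversion happens once, in the readers and writers of the
#' IO module, so there is a single place to audit off-by-one errors.
#'
#' @param seqid character vector of sequence names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param strand character vector over `"+"`, `"-"`, `"*"` (unstranded).
#' @return A `data.frame` with columns `seqid`, `start`, `end`, `strand`.
#' @examples
#' gintervals("chr1", 0L, 100L, "+")
#' @export
gintervals <- function(seqid, start, end, strand = "*") {
  df <- data.frame(seqid = as.character(seqid),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("seqid", "start", "end", "strand") %in% names(df)))
  if (any(df$start < 0L)) stop("interval start must be >= 0")
  if (any(df$start >= df$end)) stop("interval must satisfy start < end")
  if (!all(df$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  invisible(df)
}

# 0-based half-open -> IRanges (1-based inclusive)
iv_to_iranges <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

iranges_to_iv <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Union of 0-based half-open intervals on one axis
#'
#' @param start,end integer vectors (0-based half-open).
#' @return data.frame with disjoint sorted `start`, `end` columns.
#' @keywords internal
interval_union0 <- function(start, end) {
  if (length(start) == 0L) return(data.frame(start = integer(), end = integer()))
  iranges_to_iv(IRanges::reduce(iv_to_iranges(start, end)))
}

# complement of a set of disjoint covered intervals within [0, len)
interval_complement0 <- function(start, end, len) {
  if (len <= 0L) return(data.frame(start = integer(), end = integer()))
  if (length(start) == 0L) return(data.frame(start = 0L, end = as.integer(len)))
  cov <- IRanges::reduce(iv_to_iranges(start, end))
  gaps <- IRanges::setdiff(IRanges::IRanges(1L, as.integer(len)), cov)
  iranges_to_iv(gaps)
}

# total number of bases covered by the union of 0-based half-open intervals
covered_bases0 <- function(start, end) {
  u <- interval_union0(start, end)
  sum(u$end - u$start)
}
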