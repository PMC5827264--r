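#' Intron chain of a transcript
#'
#' @param tx exon table of a single transcript (sorted, non-overlapping).
#' @return data.frame of intron intervals (`start`, `end`, 0-based
#'   half-open) strictly between consecutive exons; zero rows for a
#'   single-exon transcript.
#' @export
intron_chain <- function(tx) {
  tx <- tx[order(tx$start), , drop = FALSE]
  n <- nrow(tx)
  if (n < 2L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = tx$end[-n], end = tx$start[-1L])
}

# canonical string signature of a transcript's intron chain
chain_signature <- function(tx) {
  ic <- intron_chain(tx)
  paste(sprintf("%d-%d", ic$start, ic$end), collapse = ";")
}

#' Are two gene models identical?
#'
#' Two genes count as the same gene when they lie on the same sequence
#' and strand and their transcripts describe the same splicing: the
#' multisets of intron chains of their multi-exon transcripts match
#' exactly, and their single-exon transcripts pair up by >= 1 bp exonic
#' overlap. Terminal-exon ends may differ freely; only splice junctions
#' are compared, mirroring how annotation-comparison tools call
#' transcripts equal.
#'
#' @param a,b exon tables, each containing one gene (any number of
#'   transcripts).
#' @return logical.
#' @export
genes_identical <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(FALSE)
  if (unique(a$seqid) != unique(b$seqid)) return(FALSE)
  if (unique(a$strand) != unique(b$strand)) return(FALSE)
  ta <- split_transcripts(a)
  tb <- split_transcripts(b)
  multi_a <- sort(vapply(ta[vapply(ta, nrow, 0L) > 1L], chain_signature, ""))
  multi_b <- sort(vapply(tb[vapply(tb, nrow, 0L) > 1L], chain_signature, ""))
  if (!identical(unname(multi_a), unname(multi_b))) return(FALSE)
  sa <- ta[vapply(ta, nrow, 0L) == 1L]
  sb <- tb[vapply(tb, nrow, 0L) == 1L]
  if (length(sa) != length(sb)) return(FALSE)
  if (length(sa) == 0L) return(TRUE)
  # pair i-th with i-th in start order and require overlap
  oa <- sa[order(vapply(sa, function(x) x$start, 0L))]
  ob <- sb[order(vapply(sb, function(x) x$start, 0L))]
  all(vapply(seq_along(oa), function(i) {
    oa[[i]]$start < ob[[i]]$end && ob[[i]]$start < oa[[i]]$end
  }, logical(1)))
}

# total exonic length of a gene: union of its transcripts' exons
gene_exonic_length <- function(g) {
  covered_bases0(g$start, g$end)
}

#' Merge two gene annotation models
#'
#' Builds one non-redundant annotation out of two: identical genes (see
#' [genes_identical()]) are retrieved only once, genes unique to either
#' input are carried through, and overlapping-but-different ("discordant")
#' genes are resolved by keeping the gene with the best coverage,
#' operationalised as the larger total exonic length (union of its
#' transcripts' exons); ties keep the first annotation's gene. Every
#' resolution is logged.
#'
#' @param A,B exon tables (whole annotations, any number of genes).
#' @return list with `merged` (exon table) and `log` (data.frame:
#'   `gene_a`, `gene_b`, `relation` in identical/discordant/unique,
#'   `kept`).
#' @export
merge_annotations <- function(A, B) {
  ga <- split(A, A$gene_id)
  gb <- split(B, B$gene_id)
  log <- list()
  drop_a <- character()
  keep_b <- character()

  # exon-level overlap between A and B genes, same seqid+strand
  overlaps_between <- function(x, y) {
    any(outer(seq_len(nrow(x)), seq_len(nrow(y)), function(i, j) {
      x$seqid[i] == y$seqid[j] & x$strand[i] == y$strand[j] &
        x$start[i] < y$end[j] & y$start[j] < x$end[i]
    }))
  }

  for (bid in names(gb)) {
    b <- gb[[bid]]
    ov <- names(ga)[vapply(ga, overlaps_between, logical(1), y = b)]
    if (length(ov) == 0L) {
      keep_b <- c(keep_b, bid)
      log[[length(log) + 1L]] <- data.frame(
        gene_a = NA_character_, gene_b = bid,
        relation = "unique", kept = bid, stringsAsFactors = FALSE)
      next
    }
    ident <- ov[vapply(ga[ov], genes_identical, logical(1), b = b)]
    if (length(ident) > 0L) {
      log[[length(log) + 1L]] <- data.frame(
        gene_a = ident[1L], gene_b = bid,
        relation = "identical", kept = ident[1L], stringsAsFactors = FALSE)
      next
    }
    # discordant: compare against the longest overlapping A gene
    lens_a <- vapply(ga[ov], gene_exonic_length, 0)
    best_a <- ov[which.max(lens_a)]
    len_b <- gene_exonic_length(b)
    if (len_b > max(lens_a)) {
      drop_a <- c(drop_a, best_a)
      keep_b <- c(keep_b, bid)
      kept <- bid
    } else {
      kept <- best_a  # ties keep A's gene
    }
    log[[length(log) + 1L]] <- data.frame(
      gene_a = best_a, gene_b = bid,
      relation = "discordant", kept = kept, stringsAsFactors = FALSE)
  }
  for (aid in setdiff(names(ga), drop_a)) {
    hit <- vapply(log, function(l) identical(l$gene_a, aid), logical(1))
    if (!any(hit))
      log[[length(log) + 1L]] <- data.frame(
        gene_a = aid, gene_b = NA_character_,
        relation = "unique", kept = aid, stringsAsFactors = FALSE)
  }
  merged <- rbind(
    do.call(rbind, c(ga[setdiff(names(ga), drop_a)], list(empty_exon_table()))),
    do.call(rbind, c(gb[keep_b], list(empty_exon_table()))))
  merged <- merged[order(merged$gene_id, merged$transcript_id, merged$start), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  list(merged = merged,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(gene_a = character(), gene_b = character(),
                    relation = character(), kept = character()))
}
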