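#' Strand partition of a read pair from its FLAG fields
#'
#' Under fr-firststrand chemistry the first-in-pair read is antisense to
#' the transcript, so a pair whose first mate aligns on the reverse
#' strand (equivalently, second mate forward) comes from a plus-strand
#' transcript, and vice versa. Pairs whose mates report the same
#' orientation (both forward or both reverse) are contradictory and
#' returned as `undetermined`.
#'
#' @param flag1,flag2 integer SAM FLAG values of the first and second
#'   mate (vectorised).
#' @return character vector over `"plus"`, `"minus"`, `"undetermined"`.
#' @examples
#' fragment_strand(83L, 163L)   # "plus"
#' fragment_strand(99L, 147L)   # "minus"
#' @export
fragment_strand <- function(flag1, flag2) {
  r1rev <- bitwAnd(as.integer(flag1), 16L) > 0L
  r2rev <- bitwAnd(as.integer(flag2), 16L) > 0L
  ifelse(r1rev & !r2rev, "plus",
         ifelse(r2rev & !r1rev, "minus", "undetermined"))
}

#' Count read-pair fragments over gene features
#'
#' Strand-split, duplicate-aware, chimeric-tolerant fragment counting:
#' a pair is counted for gene G when both mates overlap exon features of
#' G (by at least `min_overlap_bp`) on the strand implied by
#' [fragment_strand()] — including when the two mates lie on different
#' chromosomes or contigs, provided both locations belong to G, which is
#' exactly how fragmented genes recover their chimeric fragments. Pairs
#' flagged as PCR duplicates (0x400) are skipped when
#' `ignore_duplicates`; secondary/multi-mapping pairs (0x100) are always
#' excluded; pairs whose mates only match features of two different genes
#' are `chimeric_unresolved`; pairs matching features of two or more
#' genes at once are `ambiguous` and not counted.
#'
#' @param pairs data.frame of paired records as returned by
#'   `read_sam_min()$pairs`.
#' @param features exon table (`seqid`, `start`, `end` 0-based half-open,
#'   `strand`, `gene_id`).
#' @param require_both_ends count only pairs whose two mates both overlap
#'   the gene (default `TRUE`); when `FALSE` one overlapping mate is
#'   enough.
#' @param ignore_duplicates skip 0x400 pairs (default `TRUE`).
#' @param allow_chimeric_same_gene keep pairs whose mates map to
#'   different sequences (default `TRUE`); when `FALSE` such pairs are
#'   labelled `chimeric_unresolved` outright.
#' @param min_overlap_bp minimum per-mate overlap in bp (default 1).
#' @return list with `counts` (data.frame `gene_id`, `strand`, `count`),
#'   `labels` (per mapped pair: `query_name`, `label`, `gene_id`,
#'   `strand`) and `n_total`, `n_mapped`.
#' @export
count_fragments <- function(pairs, features, require_both_ends = TRUE,
                            ignore_duplicates = TRUE,
                            allow_chimeric_same_gene = TRUE,
                            min_overlap_bp = 1L) {
  n_total <- nrow(pairs)
  unmapped <- bitwAnd(pairs$flag1, 4L) > 0L | bitwAnd(pairs$flag2, 4L) > 0L
  mapped <- pairs[!unmapped, , drop = FALSE]
  n_mapped <- nrow(mapped)
  if (n_mapped == 0L) {
    return(list(counts = data.frame(gene_id = character(), strand = character(),
                                    count = integer()),
                labels = data.frame(query_name = character(), label = character(),
                                    gene_id = character(), strand = character()),
                n_total = n_total, n_mapped = 0L))
  }
  fstrand <- fragment_strand(mapped$flag1, mapped$flag2)
  dup <- bitwAnd(mapped$flag1, 1024L) > 0L | bitwAnd(mapped$flag2, 1024L) > 0L
  multi <- bitwAnd(mapped$flag1, 256L) > 0L | bitwAnd(mapped$flag2, 256L) > 0L

  fgr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = iv_to_iranges(features$start, features$end),
    strand = features$strand)
  gstrand <- c(plus = "+", minus = "-")
  # one findOverlaps per mate set: gene-id sets per mapped pair
  overlap_sets <- function(ref, pos, span, fs) {
    out <- rep(list(character()), length(ref))
    valid <- which(fs != "undetermined")
    if (length(valid) == 0L) return(out)
    gr <- GenomicRanges::GRanges(
      ref[valid],
      IRanges::IRanges(pos[valid], pos[valid] + span[valid] - 1L),
      strand = gstrand[fs[valid]])
    hits <- GenomicRanges::findOverlaps(gr, fgr,
                                        minoverlap = as.integer(min_overlap_bp))
    sets <- split(features$gene_id[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
    out[valid[as.integer(names(sets))]] <- lapply(sets, unique)
    out
  }
  gs1 <- overlap_sets(mapped$ref1, mapped$pos1, mapped$span1, fstrand)
  gs2 <- overlap_sets(mapped$ref2, mapped$pos2, mapped$span2, fstrand)

  labels <- character(n_mapped)
  gene <- rep(NA_character_, n_mapped)
  for (i in seq_len(n_mapped)) {
    if (ignore_duplicates && dup[i]) { labels[i] <- "duplicate"; next }
    if (multi[i]) { labels[i] <- "multimapped"; next }
    chimeric <- mapped$ref1[i] != mapped$ref2[i]
    if (chimeric && !allow_chimeric_same_gene) {
      labels[i] <- "chimeric_unresolved"; next
    }
    g1 <- gs1[[i]]
    g2 <- gs2[[i]]
    g <- if (require_both_ends) intersect(g1, g2) else union(g1, g2)
    if (length(g) == 1L) {
      labels[i] <- "assigned"; gene[i] <- g
    } else if (length(g) > 1L) {
      labels[i] <- "ambiguous"
    } else if (length(g1) > 0L && length(g2) > 0L) {
      labels[i] <- "chimeric_unresolved"
    } else {
      labels[i] <- "no_feature"
    }
  }
  assigned <- labels == "assigned"
  counts <- if (any(assigned)) {
    tab <- stats::aggregate(
      list(count = rep(1L, sum(assigned))),
      by = list(gene_id = gene[assigned], strand = fstrand[assigned]), sum)
    tab[order(tab$gene_id, tab$strand), , drop = FALSE]
  } else {
    data.frame(gene_id = character(), strand = character(), count = integer())
  }
  rownames(counts) <- NULL
  list(counts = counts,
       labels = data.frame(query_name = mapped$query_name, label = labels,
                           gene_id = gene, strand = fstrand,
                           stringsAsFactors = FALSE),
       n_total = n_total, n_mapped = n_mapped)
}

ASSIGNMENT_LABELS <- c("assigned", "ambiguous", "no_feature",
                       "chimeric_unresolved", "duplicate", "multimapped")

#' Summarise fragment assignment as an assignment-rate report
#'
#' Mirrors the structure of a read-pair assignment table: percent of
#' sequenced pairs mapped, percent assigned to gene features, percent of
#' mapped pairs not assigned, and the share of those unassigned mapped
#' pairs that overlapped no feature at all.
#'
#' @param labels character vector with one label per mapped pair, drawn
#'   from `assigned`, `ambiguous`, `no_feature`, `chimeric_unresolved`,
#'   `duplicate`, `multimapped`.
#' @param total_pairs total number of sequenced pairs (mapped + unmapped).
#' @return list of class `assignment_report`: `total_pairs`,
#'   `mapped_pairs`, `assigned_pairs`, `mapped_pct`, `assigned_pct`,
#'   `mapped_not_assigned_pct`, `no_feature_pct_of_unassigned`.
#' @export
summarize_assignment <- function(labels, total_pairs) {
  bad <- setdiff(unique(labels), ASSIGNMENT_LABELS)
  if (length(bad) > 0L) stop("unknown assignment label(s): ",
                             paste(bad, collapse = ", "))
  mapped <- length(labels)
  if (mapped > total_pairs) stop("more labelled pairs than total pairs")
  assigned <- sum(labels == "assigned")
  unassigned <- mapped - assigned
  pct <- function(num, den) if (den > 0L) 100 * num / den else 0
  structure(list(
    total_pairs = as.integer(total_pairs),
    mapped_pairs = as.integer(mapped),
    assigned_pairs = as.integer(assigned),
    mapped_pct = pct(mapped, total_pairs),
    assigned_pct = pct(assigned, total_pairs),
    mapped_not_assigned_pct = pct(unassigned, mapped),
    no_feature_pct_of_unassigned = pct(sum(labels == "no_feature"), unassigned)),
    class = "assignment_report")
}

#' @export
print.assignment_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<assignment_report>\n",
    "  total read pairs        %d\n",
    "  mapped                  %d (%.1f%%)\n",
    "  assigned to features    %d (%.1f%%)\n",
    "  mapped, not assigned    %.1f%% of mapped\n",
    "  no feature              %.1f%% of unassigned mapped\n"),
    x$total_pairs, x$mapped_pairs, x$mapped_pct,
    x$assigned_pairs, x$assigned_pct,
    x$mapped_not_assigned_pct, x$no_feature_pct_of_unassigned))
  invisible(x)
}
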