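#' Shared ungapped blocks between a consensus and an isoform
#'
#' Maximal ungapped plus-strand local matches with identity at least
#' `min_identity`, greedily selected by descending length (ties: leftmost
#' on the consensus) so that accepted blocks are mutually non-overlapping
#' on both sequences. This is the in-package equivalent of the ungapped
#' plus-strand nucleotide comparison the consensus builder is driven by.
#'
#' @param consensus_seq,isoform_seq character scalars.
#' @param min_identity minimum percent identity of a block (default 90).
#' @param min_block minimum block length in bp (default 20, a word-size
#'   scale floor that avoids spurious micro-matches).
#' @return data.frame with 0-based half-open `cons_start`, `cons_end`,
#'   `iso_start`, `iso_end`, `length`, `matches`, `pct_identity`.
#' @export
shared_blocks <- function(consensus_seq, isoform_seq, min_identity = 90,
                          min_block = 20L) {
  stopifnot(nchar(consensus_seq) > 0L, nchar(isoform_seq) > 0L)
  cand <- ungapped_matches(consensus_seq, isoform_seq,
                           min_identity = min_identity, min_len = min_block)
  cand <- cand[order(-cand$length, cand$x_start), , drop = FALSE]
  acc <- list()
  for (i in seq_len(nrow(cand))) {
    # trim the candidate out of already-accepted blocks (same diagonal on
    # both axes, so a trim moves both coordinates together); trimmed bases
    # are charged as matches, which can only lower the block's identity
    xs <- cand$x_start[i]; xe <- cand$x_end[i]
    ys <- cand$y_start[i]; ye <- cand$y_end[i]
    m <- cand$matches[i]
    ok <- TRUE
    repeat {
      changed <- FALSE
      for (a in acc) {
        if (xe - xs < 1L) { ok <- FALSE; break }
        if (xs < a$x_end && a$x_start < xe) {
          if (a$x_start <= xs) { d <- a$x_end - xs; xs <- xs + d; ys <- ys + d }
          else { d <- xe - a$x_start; xe <- xe - d; ye <- ye - d }
          m <- m - d; changed <- TRUE
        }
        if (ys < a$y_end && a$y_start < ye) {
          if (a$y_start <= ys) { d <- a$y_end - ys; ys <- ys + d; xs <- xs + d }
          else { d <- ye - a$y_start; ye <- ye - d; xe <- xe - d }
          m <- m - d; changed <- TRUE
        }
      }
      if (!ok || !changed) break
    }
    len <- xe - xs
    m <- min(m, len)
    if (!ok || len < min_block || m < 1L || 100 * m / len < min_identity) next
    acc[[length(acc) + 1L]] <- data.frame(x_start = xs, x_end = xe,
                                          y_start = ys, y_end = ye,
                                          length = len, matches = m,
                                          pct_identity = 100 * m / len)
  }
  b <- do.call(rbind, c(acc, list(data.frame(
    x_start = integer(), x_end = integer(), y_start = integer(),
    y_end = integer(), length = integer(), matches = integer(),
    pct_identity = numeric()))))
  out <- data.frame(cons_start = b$x_start, cons_end = b$x_end,
                    iso_start = b$y_start, iso_end = b$y_end,
                    length = b$length, matches = b$matches,
                    pct_identity = b$pct_identity)
  out[order(out$cons_start), , drop = FALSE]
}

#' Initialise a consensus gene from a seed isoform
#'
#' @param candidate_id gene candidate id.
#' @param isoform_id,isoform_seq the seed isoform.
#' @return object of class `consensus_gene`: list with `candidate_id`,
#'   `sequence`, per-base provenance vectors (`prov_iso`, `prov_pos`),
#'   a `support` table of per-isoform shared/unique segments (isoform
#'   coordinates) and accumulated `warnings`.
#' @export
consensus_init <- function(candidate_id, isoform_id, isoform_seq) {
  n <- nchar(isoform_seq)
  structure(list(candidate_id = candidate_id,
                 sequence = isoform_seq,
                 prov_iso = rep(isoform_id, n),
                 prov_pos = seq_len(n) - 1L,
                 support = data.frame(isoform_id = isoform_id,
                                      iso_start = 0L, iso_end = n,
                                      type = "unique", stringsAsFactors = FALSE),
                 warnings = character()),
            class = "consensus_gene")
}

#' @export
print.consensus_gene <- function(x, ...) {
  cat("<consensus_gene> ", x$candidate_id, ": ", nchar(x$sequence), " bp from ",
      length(unique(x$support$isoform_id)), " isoform(s)\n", sep = "")
  invisible(x)
}

#' Per-segment provenance of a consensus gene
#'
#' @param consensus a `consensus_gene`.
#' @return data.frame tiling the consensus without overlap: `cons_start`,
#'   `cons_end` (0-based half-open), `isoform_id`, `iso_start`, `iso_end`.
#' @export
consensus_provenance <- function(consensus) {
  r <- rle(consensus$prov_iso)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(cons_start = starts, cons_end = ends,
             isoform_id = r$values,
             iso_start = consensus$prov_pos[starts + 1L],
             iso_end = consensus$prov_pos[ends] + 1L,
             stringsAsFactors = FALSE)
}

#' Merge one isoform into a consensus gene
#'
#' Shared segments (the blocks) appear once; isoform segments outside the
#' blocks are inserted into the consensus at the position of the flanking
#' shared block — a segment before the first block immediately before
#' that block, segments between blocks at the upstream block's end, and a
#' segment after the last block immediately after it. Inserting next to
#' the flanking block (rather than at the absolute consensus ends)
#' preserves transcriptional order when the consensus already extends
#' beyond the shared chain. An isoform with no shared block at all is
#' appended whole: sequence unique to a single transcript is deliberately
#' retained, never dropped. If the blocks are not colinear on both
#' sequences (a rearrangement, which an ungapped plus-strand merge cannot
#' represent), the largest colinear chain is kept and the rest dropped
#' with a warning.
#'
#' @param consensus a `consensus_gene`.
#' @param isoform_id,isoform_seq the isoform to fold in.
#' @param blocks output of [shared_blocks()] for
#'   `(consensus$sequence, isoform_seq)`.
#' @return the updated `consensus_gene`.
#' @export
merge_isoform <- function(consensus, isoform_id, isoform_seq, blocks) {
  n_iso <- nchar(isoform_seq)
  if (is.null(blocks) || nrow(blocks) == 0L) {
    ins <- data.frame(pos = nchar(consensus$sequence),
                      iso_start = 0L, iso_end = n_iso)
    return(splice_insertions(consensus, isoform_id, isoform_seq, ins,
                             shared = blocks[0, ]))
  }
  blocks <- blocks[order(blocks$cons_start), , drop = FALSE]
  chain <- largest_colinear_chain(blocks)
  if (nrow(chain) < nrow(blocks)) {
    consensus$warnings <- c(consensus$warnings, sprintf(
      "%s: %d non-colinear block(s) dropped while merging %s",
      consensus$candidate_id, nrow(blocks) - nrow(chain), isoform_id))
  }
  ins <- list()
  if (chain$iso_start[1L] > 0L)
    ins[[length(ins) + 1L]] <- data.frame(pos = chain$cons_start[1L],
                                          iso_start = 0L,
                                          iso_end = chain$iso_start[1L])
  if (nrow(chain) > 1L) {
    for (i in seq_len(nrow(chain) - 1L)) {
      if (chain$iso_start[i + 1L] > chain$iso_end[i])
        ins[[length(ins) + 1L]] <- data.frame(pos = chain$cons_end[i],
                                              iso_start = chain$iso_end[i],
                                              iso_end = chain$iso_start[i + 1L])
    }
  }
  nlast <- nrow(chain)
  if (chain$iso_end[nlast] < n_iso)
    ins[[length(ins) + 1L]] <- data.frame(pos = chain$cons_end[nlast],
                                          iso_start = chain$iso_end[nlast],
                                          iso_end = n_iso)
  ins <- if (length(ins)) do.call(rbind, ins) else
    data.frame(pos = integer(), iso_start = integer(), iso_end = integer())
  splice_insertions(consensus, isoform_id, isoform_seq, ins, shared = chain)
}

# maximum-total-length chain of blocks increasing on both axes
largest_colinear_chain <- function(blocks) {
  n <- nrow(blocks)
  if (n <= 1L) return(blocks)
  best <- blocks$length
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (blocks$cons_end[j] <= blocks$cons_start[i] &&
          blocks$iso_end[j] <= blocks$iso_start[i] &&
          best[j] + blocks$length[i] > best[i]) {
        best[i] <- best[j] + blocks$length[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  idx <- integer()
  while (!is.na(i)) { idx <- c(i, idx); i <- prev[i] }
  blocks[idx, , drop = FALSE]
}

# apply insertions (positions on the current consensus) and bookkeeping
splice_insertions <- function(consensus, isoform_id, isoform_seq, ins, shared) {
  seq_old <- consensus$sequence
  ins <- ins[order(ins$pos), , drop = FALSE]
  pieces <- character(); prov_iso <- list(); prov_pos <- list()
  cur <- 0L
  for (i in seq_len(nrow(ins))) {
    p <- ins$pos[i]
    if (p > cur) {
      pieces <- c(pieces, substring(seq_old, cur + 1L, p))
      prov_iso[[length(prov_iso) + 1L]] <- consensus$prov_iso[(cur + 1L):p]
      prov_pos[[length(prov_pos) + 1L]] <- consensus$prov_pos[(cur + 1L):p]
    }
    seg <- substring(isoform_seq, ins$iso_start[i] + 1L, ins$iso_end[i])
    pieces <- c(pieces, seg)
    prov_iso[[length(prov_iso) + 1L]] <- rep(isoform_id, nchar(seg))
    prov_pos[[length(prov_pos) + 1L]] <- seq.int(ins$iso_start[i],
                                                 ins$iso_end[i] - 1L)
    cur <- p
  }
  if (cur < nchar(seq_old)) {
    pieces <- c(pieces, substring(seq_old, cur + 1L, nchar(seq_old)))
    prov_iso[[length(prov_iso) + 1L]] <- consensus$prov_iso[(cur + 1L):nchar(seq_old)]
    prov_pos[[length(prov_pos) + 1L]] <- consensus$prov_pos[(cur + 1L):nchar(seq_old)]
  }
  consensus$sequence <- paste(pieces, collapse = "")
  consensus$prov_iso <- unlist(prov_iso, use.names = FALSE)
  consensus$prov_pos <- unlist(prov_pos, use.names = FALSE)
  sup <- list()
  if (nrow(shared) > 0L)
    sup[[1L]] <- data.frame(isoform_id = isoform_id,
                            iso_start = shared$iso_start,
                            iso_end = shared$iso_end,
                            type = "shared", stringsAsFactors = FALSE)
  if (nrow(ins) > 0L)
    sup[[length(sup) + 1L]] <- data.frame(isoform_id = isoform_id,
                                          iso_start = ins$iso_start,
                                          iso_end = ins$iso_end,
                                          type = "unique",
                                          stringsAsFactors = FALSE)
  if (length(sup) == 0L)  # isoform entirely covered by shared blocks
    sup[[1L]] <- data.frame(isoform_id = isoform_id, iso_start = 0L,
                            iso_end = nchar(isoform_seq), type = "shared",
                            stringsAsFactors = FALSE)
  consensus$support <- rbind(consensus$support, do.call(rbind, sup))
  consensus
}

#' Build the consensus (superTranscript-like) sequence of a gene candidate
#'
#' Seeds the consensus with the longest isoform (ties broken by
#' lexicographic id) and folds the remaining isoforms in descending
#' length order through [shared_blocks()] + [merge_isoform()], so that
#' every distinct isoform block appears exactly once and sequence unique
#' to any isoform is retained.
#'
#' @param candidate_id gene candidate id.
#' @param isoforms named character vector of isoform sequences.
#' @param min_identity,min_block passed to [shared_blocks()].
#' @return a `consensus_gene`.
#' @export
build_consensus <- function(candidate_id, isoforms, min_identity = 90,
                            min_block = 20L) {
  stopifnot(length(isoforms) >= 1L, !is.null(names(isoforms)))
  ord <- order(-nchar(isoforms), names(isoforms))
  isoforms <- isoforms[ord]
  cons <- consensus_init(candidate_id, names(isoforms)[1L], isoforms[[1L]])
  for (i in seq_along(isoforms)[-1L]) {
    blocks <- shared_blocks(cons$sequence, isoforms[[i]],
                            min_identity = min_identity, min_block = min_block)
    cons <- merge_isoform(cons, names(isoforms)[i], isoforms[[i]], blocks)
  }
  cons
}

#' Concatenate sequences into an artificial chromosome
#'
#' Retained de novo sequences absent from the genome are gathered into
#' one artificial chromosome, separated by runs of N whose length equals
#' the total span of a read pair (2 x 50 bp reads + 150 bp insert =
#' 250 bp by default), so no read pair can bridge two genes.
#'
#' @param sequences named character vector (candidate_id -> sequence), in
#'   the order they should appear.
#' @param spacer N-spacer length in bp (default 250).
#' @param name chromosome name.
#' @return list of class `artificial_chromosome` with `name`, `sequence`,
#'   `features` (data.frame: `candidate_id`, `start`, `end`, 0-based
#'   half-open) and `spacer_length`.
#' @export
build_artificial_chromosome <- function(sequences, spacer = 250L,
                                        name = "chrU_denovo") {
  stopifnot(length(sequences) >= 1L, !is.null(names(sequences)))
  if (any(nchar(sequences) == 0L))
    stop("empty sequence for ", names(sequences)[nchar(sequences) == 0L][1L])
  lens <- nchar(sequences)
  starts <- cumsum(c(0L, utils::head(lens, -1L) + spacer))
  sep <- strrep("N", spacer)
  structure(list(
    name = name,
    sequence = paste(unname(sequences), collapse = sep),
    features = data.frame(candidate_id = names(sequences),
                          start = as.integer(starts),
                          end = as.integer(starts + lens),
                          stringsAsFactors = FALSE),
    spacer_length = as.integer(spacer)),
    class = "artificial_chromosome")
}

#' @export
print.artificial_chromosome <- function(x, ...) {
  cat("<artificial_chromosome> ", x$name, ": ", nchar(x$sequence), " bp, ",
      nrow(x$features), " feature(s), spacer ", x$spacer_length, " bp\n",
      sep = "")
  invisible(x)
}

#' Write an artificial chromosome as FASTA + GTF
#'
#' @param chrom an `artificial_chromosome`.
#' @param fasta_path,gtf_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_artificial_chromosome <- function(chrom, fasta_path, gtf_path) {
  seqs <- stats::setNames(chrom$sequence, chrom$name)
  write_fasta(seqs, fasta_path)
  exons <- data.frame(seqid = chrom$name, start = chrom$features$start,
                      end = chrom$features$end, strand = "+",
                      gene_id = chrom$features$candidate_id,
                      transcript_id = chrom$features$candidate_id,
                      source = "dualtx", stringsAsFactors = FALSE)
  write_gtf(exons, gtf_path)
  invisible(list(fasta = fasta_path, gtf = gtf_path))
}
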