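#' Union coverage of alignment hits on one axis
#'
#' @param hits `hits_tab` data.frame whose rows all share the chosen axis
#'   id (an error otherwise).
#' @param axis `"query"` or `"subject"`.
#' @return A `coverage_map`: list with `target_id`, `covered` (data.frame
#'   of disjoint sorted 0-based half-open intervals).
#' @export
coverage_union <- function(hits, axis = c("query", "subject")) {
  axis <- match.arg(axis)
  idc <- if (axis == "query") hits$query_id else hits$subject_id
  if (nrow(hits) == 0L) {
    return(structure(list(target_id = NA_character_,
                          covered = data.frame(start = integer(), end = integer())),
                     class = "coverage_map"))
  }
  if (length(unique(idc)) != 1L)
    stop("hits mix several ", axis, " ids: ", paste(unique(idc), collapse = ", "))
  s <- if (axis == "query") hits$q_start else hits$s_start
  e <- if (axis == "query") hits$q_end else hits$s_end
  structure(list(target_id = idc[1L],
                 covered = interval_union0(s - 1L, e)),
            class = "coverage_map")
}

#' Assign a de novo contig to gene candidates by novel coverage
#'
#' Hits of one contig against the gene-candidate sequences are processed
#' in a fixed order (descending bit score, then ascending e-value, then
#' subject id); a hit is accepted only if its percent identity is
#' strictly greater than `min_identity` and it contributes at least
#' `min_novel_bp` bases not covered by any previously accepted hit.
#' Novelty is counted on the contig (query) axis by default; the
#' `axis = "subject"` alternative keeps one running coverage map per gene
#' candidate instead.
#'
#' @param contig_id contig (query) id; all hits must carry it.
#' @param hits `hits_tab` rows for this contig.
#' @param min_identity strict lower bound on percent identity (default 90).
#' @param min_novel_bp minimum novel bases per accepted hit (default 40).
#' @param axis axis on which novelty is measured.
#' @return list with `assignments` (data.frame: `contig_id`,
#'   `gene_candidate_id`, `n_hits`, `novel_bp`), `accepted_hits` (the
#'   accepted `hits_tab` rows) and `coverage` (the final query-axis
#'   `coverage_map`).
#' @export
assign_contig <- function(contig_id, hits, min_identity = 90,
                          min_novel_bp = 40L, axis = c("query", "subject")) {
  axis <- match.arg(axis)
  if (nrow(hits) > 0L && any(hits$query_id != contig_id))
    stop("hits for a different contig than ", contig_id)
  ord <- order(-hits$bitscore, hits$evalue, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  cov_q <- data.frame(start = integer(), end = integer())   # query axis
  cov_s <- list()                                           # per-subject maps
  accepted <- logical(nrow(hits))
  novel_bp <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!(hits$pct_identity[i] > min_identity)) next
    if (axis == "query") {
      s0 <- hits$q_start[i] - 1L; e0 <- hits$q_end[i]
      new_cov <- interval_union0(c(cov_q$start, s0), c(cov_q$end, e0))
      novel <- sum(new_cov$end - new_cov$start) - sum(cov_q$end - cov_q$start)
      if (novel >= min_novel_bp) {
        accepted[i] <- TRUE; novel_bp[i] <- novel; cov_q <- new_cov
      }
    } else {
      sid <- hits$subject_id[i]
      old <- cov_s[[sid]]
      if (is.null(old)) old <- data.frame(start = integer(), end = integer())
      s0 <- hits$s_start[i] - 1L; e0 <- hits$s_end[i]
      new_cov <- interval_union0(c(old$start, s0), c(old$end, e0))
      novel <- sum(new_cov$end - new_cov$start) - sum(old$end - old$start)
      if (novel >= min_novel_bp) {
        accepted[i] <- TRUE; novel_bp[i] <- novel; cov_s[[sid]] <- new_cov
      }
    }
  }
  acc <- hits[accepted, , drop = FALSE]
  if (nrow(acc) > 0L) {
    agg <- stats::aggregate(cbind(n_hits = rep(1L, nrow(acc)),
                                  novel_bp = novel_bp[accepted]),
                            by = list(gene_candidate_id = acc$subject_id), sum)
    assignments <- data.frame(contig_id = contig_id,
                              gene_candidate_id = agg$gene_candidate_id,
                              n_hits = agg$n_hits, novel_bp = agg$novel_bp,
                              stringsAsFactors = FALSE)
  } else {
    assignments <- data.frame(contig_id = character(),
                              gene_candidate_id = character(),
                              n_hits = integer(), novel_bp = integer(),
                              stringsAsFactors = FALSE)
  }
  final_cov_q <- coverage_union(acc[acc$query_id == contig_id, , drop = FALSE],
                                axis = "query")
  if (nrow(acc) == 0L)
    final_cov_q <- structure(list(target_id = contig_id,
                                  covered = data.frame(start = integer(),
                                                       end = integer())),
                             class = "coverage_map")
  list(assignments = assignments, accepted_hits = acc, coverage = final_cov_q)
}

#' Continuous uncovered regions of a target sequence
#'
#' Complements a coverage map within `[0, target_length)` and keeps
#' maximal uncovered runs of at least `min_len` bases (runs touching
#' either end of the target included). When the target sequence is
#' supplied, runs of ambiguous bases (N) count as uncoverable: they are
#' treated as covered so that assembly-gap sequence can neither extend
#' nor constitute a "novel" region.
#'
#' @param target_length length of the target in bp.
#' @param cov a `coverage_map` on the target's own coordinates.
#' @param min_len minimum region length (default 400).
#' @param target_seq optional target sequence (character scalar).
#' @return data.frame of sorted 0-based half-open intervals.
#' @export
uncovered_regions <- function(target_length, cov, min_len = 400L,
                              target_seq = NULL) {
  covered <- cov$covered
  if (!is.null(target_seq)) {
    nruns <- n_runs(target_seq)
    covered <- interval_union0(c(covered$start, nruns$start),
                               c(covered$end, nruns$end))
  }
  gaps <- interval_complement0(covered$start, covered$end, target_length)
  gaps[gaps$end - gaps$start >= min_len, , drop = FALSE]
}

# 0-based half-open runs of N/n in a sequence
n_runs <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  r <- rle(chars == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Classify where an unassigned contig lands on the genome
#'
#' A contig that maps strictly between two consecutive features of a gene
#' candidate potentially corresponds to an exon missed by the
#' genome-guided prediction (`internal_exon`); one mapping within
#' `vicinity_bp` upstream of the first or downstream of the last feature
#' (in transcriptional order, i.e. strand-aware) is a candidate missing
#' 5'- or 3'-UTR (`five_prime_extension` / `three_prime_extension`);
#' anything else is `unplaced`. The contig's genomic interval is taken
#' from its best (highest bit score) genome hit.
#'
#' @param contig_hits_on_genome `hits_tab` of the contig vs the genome.
#' @param candidate_features interval data.frame (one seqid, one strand)
#'   of the candidate's features in genomic coordinates.
#' @param vicinity_bp how far beyond the terminal features to look
#'   (default 10000).
#' @return one of `"internal_exon"`, `"five_prime_extension"`,
#'   `"three_prime_extension"`, `"unplaced"`.
#' @export
classify_genomic_placement <- function(contig_hits_on_genome,
                                       candidate_features,
                                       vicinity_bp = 10000L) {
  if (nrow(contig_hits_on_genome) == 0L) return("unplaced")
  best <- contig_hits_on_genome[which.max(contig_hits_on_genome$bitscore), ]
  seqid <- best$subject_id
  s0 <- best$s_start - 1L
  e0 <- best$s_end
  f <- candidate_features
  if (!all(f$seqid == f$seqid[1L]))
    stop("candidate features must share one sequence")
  if (seqid != f$seqid[1L]) return("unplaced")
  strand <- f$strand[1L]
  f <- f[order(f$start), , drop = FALSE]
  n <- nrow(f)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (s0 >= f$end[i] && e0 <= f$start[i + 1L]) return("internal_exon")
    }
  }
  left <- e0 <= f$start[1L] && s0 >= f$start[1L] - vicinity_bp
  right <- s0 >= f$end[n] && e0 <= f$end[n] + vicinity_bp
  if (strand == "-") {
    if (right) return("five_prime_extension")
    if (left) return("three_prime_extension")
  } else {
    if (left) return("five_prime_extension")
    if (right) return("three_prime_extension")
  }
  "unplaced"
}

#' Fragmentation class of a gene candidate
#'
#' Mirrors the four location categories of the corrected gene model:
#' all parts on one sequence (`single_location`); parts on several
#' ordered chromosomes (`multi_ordered`); parts split among several
#' unplaced contigs (`multi_unplaced`); and parts on both kinds of
#' sequence (`mixed`, which also covers parts on an artificial
#' chromosome).
#'
#' @param parts data.frame of candidate parts with a `seqid` column.
#' @param chrom_class named character vector mapping seqid to
#'   `"ordered"`, `"unplaced"` or `"artificial"`.
#' @return one of `"single_location"`, `"multi_ordered"`,
#'   `"multi_unplaced"`, `"mixed"`.
#' @export
fragmentation_class <- function(parts, chrom_class) {
  if (nrow(parts) == 0L) stop("candidate with no parts")
  seqs <- unique(parts$seqid)
  if (length(seqs) == 1L) return("single_location")
  cls <- chrom_class[seqs]
  if (anyNA(cls)) stop("unknown chromosome class for: ",
                       paste(seqs[is.na(cls)], collapse = ", "))
  if (all(cls == "ordered")) return("multi_ordered")
  if (all(cls == "unplaced")) return("multi_unplaced")
  "mixed"
}

#' Attach assigned contig locations to their gene candidates
#'
#' Appends every assigned contig's genomic location(s) to the owning
#' candidate's parts, deduplicating by (seqid, interval). Candidate
#' identity is never split or merged here; a contig assigned to two or
#' more candidates is recorded in a conflicts report and its locations
#' are still appended to each of them, leaving the resolution to the
#' analyst.
#'
#' @param assignments data.frame with `contig_id`, `gene_candidate_id`.
#' @param candidate_parts data.frame with `candidate_id`, `seqid`,
#'   `start`, `end` (0-based half-open).
#' @param contig_locations data.frame with `contig_id`, `seqid`, `start`,
#'   `end` — where each contig sits on the genome (possibly several rows).
#' @return list with `parts` (updated candidate parts) and `conflicts`
#'   (data.frame: `contig_id`, `candidate_ids`).
#' @export
gather_parts <- function(assignments, candidate_parts, contig_locations) {
  conflicts <- data.frame(contig_id = character(), candidate_ids = character(),
                          stringsAsFactors = FALSE)
  if (nrow(assignments) == 0L)
    return(list(parts = candidate_parts, conflicts = conflicts))
  by_contig <- split(assignments$gene_candidate_id, assignments$contig_id)
  multi <- names(by_contig)[lengths(lapply(by_contig, unique)) > 1L]
  if (length(multi) > 0L)
    conflicts <- data.frame(
      contig_id = multi,
      candidate_ids = vapply(by_contig[multi],
                             function(x) paste(sort(unique(x)), collapse = ","), ""),
      stringsAsFactors = FALSE)
  new_rows <- merge(assignments, contig_locations, by = "contig_id")
  if (nrow(new_rows) > 0L) {
    add <- data.frame(candidate_id = new_rows$gene_candidate_id,
                      seqid = new_rows$seqid,
                      start = new_rows$start, end = new_rows$end,
                      stringsAsFactors = FALSE)
    parts <- rbind(candidate_parts[, c("candidate_id", "seqid", "start", "end")],
                   add)
  } else {
    parts <- candidate_parts[, c("candidate_id", "seqid", "start", "end")]
  }
  parts <- unique(parts)
  parts <- parts[order(parts$candidate_id, parts$seqid, parts$start), ,
                 drop = FALSE]
  rownames(parts) <- NULL
  list(parts = parts, conflicts = conflicts)
}
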