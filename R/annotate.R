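#' Bidirectional coverage of a candidate/subject hit group
#'
#' Union coverage of the mutual alignment hits on each axis, as a percent
#' of the respective sequence length.
#'
#' @param candidate_len,subject_len lengths in bp.
#' @param hits `hits_tab` rows for one candidate/subject pair.
#' @return numeric vector `c(query_cov_pct, subject_cov_pct)`.
#' @export
bidirectional_coverage <- function(candidate_len, subject_len, hits) {
  if (nrow(hits) == 0L) return(c(query_cov_pct = 0, subject_cov_pct = 0))
  qc <- covered_bases0(hits$q_start - 1L, hits$q_end)
  sc <- covered_bases0(hits$s_start - 1L, hits$s_end)
  c(query_cov_pct = 100 * qc / candidate_len,
    subject_cov_pct = 100 * sc / subject_len)
}

#' Nucleotide-tier gene naming
#'
#' First tier of the annotation cascade: a subject gene qualifies when
#' its identity clears the taxon-specific bar — strictly greater than
#' `chicken_min_id` for same-species (chicken) genes, at least
#' `bird_min_id` for other bird genes (the asymmetry follows the rule's
#' original wording) — and the candidate and subject are each covered on
#' at least `min_bidir_cov` percent of their length by the union of their
#' mutual hits. Among qualifying gene names the highest total bit score
#' wins; if several distinct names qualify the call is flagged discordant
#' (chimeric/fused candidates go to a manual-review queue).
#'
#' @param candidate_id candidate id (hits' query).
#' @param candidate_len candidate length (bp).
#' @param nt_hits `hits_tab` with extra columns `gene_name`, `taxon`
#'   (`"chicken"` or `"other_bird"`) and `subject_len`.
#' @param chicken_min_id strict identity bound for chicken genes (default 90).
#' @param bird_min_id inclusive identity bound for other birds (default 75).
#' @param min_bidir_cov minimum percent coverage on both axes (default 50).
#' @return list: `name` (or `NA`), `tier` (`"nt"`), `discordant` flag,
#'   `qualifying` (character vector of qualifying names).
#' @export
assign_name_nt <- function(candidate_id, candidate_len, nt_hits,
                           chicken_min_id = 90, bird_min_id = 75,
                           min_bidir_cov = 50) {
  no_call <- list(name = NA_character_, tier = "nt", discordant = FALSE,
                  qualifying = character())
  if (nrow(nt_hits) == 0L) return(no_call)
  stopifnot(all(c("gene_name", "taxon", "subject_len") %in% names(nt_hits)))
  if (any(nt_hits$query_id != candidate_id))
    stop("nt hits for a different candidate than ", candidate_id)
  groups <- split(seq_len(nrow(nt_hits)), nt_hits$gene_name)
  qual <- character(); score <- numeric()
  for (nm in names(groups)) {
    h <- nt_hits[groups[[nm]], , drop = FALSE]
    id_ok <- any(ifelse(h$taxon == "chicken",
                        h$pct_identity > chicken_min_id,
                        h$pct_identity >= bird_min_id))
    if (!id_ok) next
    # coverage per subject sequence; the best-covered subject represents the name
    cov_ok <- any(vapply(split(seq_len(nrow(h)), h$subject_id), function(i) {
      hh <- h[i, , drop = FALSE]
      bc <- bidirectional_coverage(candidate_len, hh$subject_len[1L], hh)
      all(bc >= min_bidir_cov)
    }, logical(1)))
    if (!cov_ok) next
    qual <- c(qual, nm)
    score <- c(score, sum(h$bitscore))
  }
  if (length(qual) == 0L) return(no_call)
  ord <- order(-score, qual)  # bitscore, then alphabetical for determinism
  list(name = qual[ord[1L]], tier = "nt",
       discordant = length(qual) > 1L, qualifying = qual[ord])
}

#' Protein-tier gene naming
#'
#' Second tier, applied to candidates the nucleotide tier left unnamed:
#' protein hits qualify when their percent homology (the positives
#' fraction of the protein alignment) is at least `min_homology` and the
#' candidate is covered on at least `min_cov` percent of its length.
#' Protein accessions are converted to gene names through a static
#' accession map; hits whose accession is absent from the map are ignored
#' with a warning. The name with the best total bit score wins.
#'
#' @param candidate_id,candidate_len candidate id and length.
#' @param prot_hits `hits_tab` with a `pct_homology` column; `subject_id`
#'   holds the protein accession.
#' @param accession_map data.frame with columns `accession`, `gene_name`.
#' @param min_homology minimum percent homology (default 30, inclusive).
#' @param min_cov minimum percent query coverage (default 50).
#' @return list: `name` (or `NA`), `tier` (`"protein"`).
#' @export
assign_name_prot <- function(candidate_id, candidate_len, prot_hits,
                             accession_map, min_homology = 30, min_cov = 50) {
  no_call <- list(name = NA_character_, tier = "protein")
  if (nrow(prot_hits) == 0L) return(no_call)
  stopifnot("pct_homology" %in% names(prot_hits))
  unmapped <- setdiff(unique(prot_hits$subject_id), accession_map$accession)
  if (length(unmapped) > 0L) {
    warning("ignoring hits to unmapped accession(s): ",
            paste(unmapped, collapse = ", "))
    prot_hits <- prot_hits[!prot_hits$subject_id %in% unmapped, , drop = FALSE]
  }
  if (nrow(prot_hits) == 0L) return(no_call)
  prot_hits$gene_name <- accession_map$gene_name[
    match(prot_hits$subject_id, accession_map$accession)]
  groups <- split(seq_len(nrow(prot_hits)), prot_hits$gene_name)
  qual <- character(); score <- numeric()
  for (nm in names(groups)) {
    h <- prot_hits[groups[[nm]], , drop = FALSE]
    if (!any(h$pct_homology >= min_homology)) next
    qcov <- 100 * covered_bases0(h$q_start - 1L, h$q_end) / candidate_len
    if (qcov < min_cov) next
    qual <- c(qual, nm); score <- c(score, sum(h$bitscore))
  }
  if (length(qual) == 0L) return(no_call)
  list(name = qual[order(-score, qual)][1L], tier = "protein")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames
#'
#' Scans the three forward frames (forward only under strand-specific
#' mode, matching a stranded library) and reports maximal ORFs: complete
#' ORFs from the first ATG after the previous stop to the next stop,
#' 3'-partial ORFs running off the end of the sequence, and a 5'-partial
#' ORF when the first stop of a frame is reached without any upstream
#' ATG. ORF length counts codons from the start codon, excluding the
#' stop.
#'
#' @param sequence nucleotide text (length >= 3).
#' @param strand_specific scan forward frames only (default `TRUE`); when
#'   `FALSE` the reverse complement's frames are scanned too.
#' @param min_aa minimum ORF length to report (default 1 aa).
#' @return data.frame sorted by `length_aa` descending: `frame` (0/1/2),
#'   `strand`, `start`, `end` (0-based half-open nt coordinates on the
#'   given sequence, stop codon excluded), `length_aa`, `completeness`.
#' @export
find_orfs <- function(sequence, strand_specific = TRUE, min_aa = 1L) {
  stopifnot(nchar(sequence) >= 3L)
  scan1 <- function(seq, strand) {
    n <- nchar(seq)
    out <- list()
    for (f in 0:2) {
      starts <- seq.int(f + 1L, n - 2L, by = 3L)
      if (length(starts) == 0L) next
      codons <- substring(toupper(seq), starts, starts + 2L)
      is_stop <- codons %in% STOP_CODONS
      is_atg <- codons == "ATG"
      seg_start <- 1L
      stops <- c(which(is_stop), length(codons) + 1L)
      for (s in stops) {
        idx <- seq_len(s - seg_start) + seg_start - 1L
        has_stop <- s <= length(codons)
        atg <- idx[is_atg[idx]][1L]
        if (!is.na(atg)) {
          out[[length(out) + 1L]] <- data.frame(
            frame = f, strand = strand,
            start = starts[atg] - 1L, end = starts[atg] - 1L + 3L * (s - atg),
            length_aa = s - atg,
            completeness = if (has_stop) "complete" else "three_prime_partial",
            stringsAsFactors = FALSE)
        } else if (seg_start == 1L && length(idx) > 0L && has_stop) {
          # frame start reached a stop with no upstream ATG: 5'-partial
          # (a frame with neither ATG nor stop carries no ORF evidence)
          out[[length(out) + 1L]] <- data.frame(
            frame = f, strand = strand,
            start = starts[idx[1L]] - 1L,
            end = starts[idx[1L]] - 1L + 3L * length(idx),
            length_aa = length(idx),
            completeness = "five_prime_partial", stringsAsFactors = FALSE)
        }
        seg_start <- s + 1L
      }
    }
    out
  }
  res <- scan1(sequence, "+")
  if (!strand_specific)
    res <- c(res, scan1(revcomp(sequence), "-"))
  res <- do.call(rbind, c(res, list(data.frame(
    frame = integer(), strand = character(), start = integer(),
    end = integer(), length_aa = integer(), completeness = character(),
    stringsAsFactors = FALSE))))
  res <- res[res$length_aa >= min_aa, , drop = FALSE]
  res <- res[order(-res$length_aa, res$frame, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Biotype classification cascade
#'
#' Total decision cascade over the annotation evidence of one candidate:
#' (1) a name matching a miscellaneous keyword (ribosomal RNA,
#' spliceosomal, pseudogene, ...) makes the candidate `miscellaneous`;
#' (2) any other name makes it `protein_coding_named`; unnamed candidates
#' with a longest ORF of at least `min_orf_aa` amino acids are
#' (3) `putative_protein` when any protein domain, signal peptide or
#' transmembrane domain was predicted, otherwise
#' (4) `uncharacterized_protein`; (5) everything else (no sufficient ORF)
#' is `ncRNA`.
#'
#' @param evidence list with `name` (or `NA`), `name_tier`,
#'   `longest_orf_aa`, `has_domain`, `has_signal_peptide`, `has_tm_domain`.
#' @param misc_keywords regular expressions matched case-insensitively
#'   against the name.
#' @param min_orf_aa ORF threshold in amino acids (default 100).
#' @return list (`biotype_call`): `biotype`, `name`, `evidence_tier`.
#' @export
classify_biotype <- function(evidence,
                             misc_keywords = c("rRNA", "ribosomal RNA",
                                               "spliceosom", "pseudogene",
                                               "snRNA"),
                             min_orf_aa = 100L) {
  named <- !is.na(evidence$name) && nzchar(evidence$name)
  if (named) {
    misc <- any(vapply(misc_keywords, function(k)
      grepl(k, evidence$name, ignore.case = TRUE), logical(1)))
    if (misc)
      return(list(biotype = "miscellaneous", name = evidence$name,
                  evidence_tier = "misc_keyword"))
    return(list(biotype = "protein_coding_named", name = evidence$name,
                evidence_tier = evidence$name_tier))
  }
  orf_aa <- evidence$longest_orf_aa
  if (length(orf_aa) == 0L || is.na(orf_aa)) orf_aa <- 0L
  if (orf_aa >= min_orf_aa) {
    if (isTRUE(evidence$has_domain) || isTRUE(evidence$has_signal_peptide) ||
        isTRUE(evidence$has_tm_domain))
      return(list(biotype = "putative_protein", name = NA_character_,
                  evidence_tier = "orf_domain"))
    return(list(biotype = "uncharacterized_protein", name = NA_character_,
                evidence_tier = "orf_only"))
  }
  list(biotype = "ncRNA", name = NA_character_, evidence_tier = "no_orf")
}

#' Length coverage of a candidate by reference genes
#'
#' @param candidate_len candidate length (bp).
#' @param ref_hits `hits_tab` rows with the candidate as query.
#' @return list: `pct_covered` and `bin` in `"zero"` (no hits at all),
#'   `"below_50"`, `"at_least_50"`.
#' @export
coverage_vs_reference <- function(candidate_len, ref_hits) {
  if (nrow(ref_hits) == 0L)
    return(list(pct_covered = 0, bin = "zero"))
  pct <- 100 * covered_bases0(ref_hits$q_start - 1L, ref_hits$q_end) /
    candidate_len
  list(pct_covered = pct, bin = if (pct >= 50) "at_least_50" else "below_50")
}

#' Gene-name concordance against a reference annotation
#'
#' Restricts to reference genes whose hits cover at least `min_len_cov`
#' percent of the candidate's length; the best such gene (highest total
#' bit score) is compared to the candidate's name case-insensitively
#' after applying a synonym table.
#'
#' @param candidate_name candidate's assigned name (`NA` if unnamed).
#' @param candidate_len candidate length (bp).
#' @param ref_hits `hits_tab` with a `gene_name` column (`NA` for hits to
#'   unnamed reference loci).
#' @param min_len_cov minimum percent length coverage (default 50).
#' @param synonyms optional data.frame (`name`, `canonical`) applied to
#'   both sides before comparison.
#' @return one of `"concordant"`, `"discordant"`, `"matched_undefined"`,
#'   `"no_match"`.
#' @export
name_concordance <- function(candidate_name, candidate_len, ref_hits,
                             min_len_cov = 50, synonyms = NULL) {
  if (nrow(ref_hits) == 0L) return("no_match")
  stopifnot("gene_name" %in% names(ref_hits))
  keyed <- ifelse(is.na(ref_hits$gene_name), "<undefined>", ref_hits$gene_name)
  groups <- split(seq_len(nrow(ref_hits)), keyed)
  qual <- character(); score <- numeric()
  for (nm in names(groups)) {
    h <- ref_hits[groups[[nm]], , drop = FALSE]
    cov <- 100 * covered_bases0(h$q_start - 1L, h$q_end) / candidate_len
    if (cov >= min_len_cov) { qual <- c(qual, nm); score <- c(score, sum(h$bitscore)) }
  }
  if (length(qual) == 0L) return("no_match")
  best <- qual[order(-score, qual)][1L]
  if (best == "<undefined>") return("matched_undefined")
  canon <- function(x) {
    x <- toupper(x)
    if (!is.null(synonyms)) {
      i <- match(x, toupper(synonyms$name))
      x[!is.na(i)] <- toupper(synonyms$canonical[i[!is.na(i)]])
    }
    x
  }
  if (!is.na(candidate_name) && canon(candidate_name) == canon(best))
    "concordant" else "discordant"
}

#' Run the full naming + biotype cascade over a candidate set
#'
#' Convenience driver: nucleotide tier first, protein tier for candidates
#' left unnamed, ORF scan, then [classify_biotype()].
#'
#' @param candidates named character vector of candidate sequences.
#' @param nt_hits `hits_tab` (+ `gene_name`, `taxon`, `subject_len`) for
#'   all candidates, or `NULL`.
#' @param prot_hits `hits_tab` (+ `pct_homology`) or `NULL`.
#' @param accession_map accession-to-gene-name table (see
#'   [assign_name_prot()]).
#' @param domain_evidence optional data.frame with `candidate_id`,
#'   `has_domain`, `has_signal_peptide`, `has_tm_domain`.
#' @param ... passed to [assign_name_nt()] and [classify_biotype()].
#' @return data.frame: `candidate_id`, `name`, `biotype`,
#'   `evidence_tier`, `longest_orf_aa`, `discordant`.
#' @export
annotate_candidates <- function(candidates, nt_hits = NULL, prot_hits = NULL,
                                accession_map = NULL, domain_evidence = NULL,
                                ...) {
  dots <- list(...)
  nt_args <- dots[names(dots) %in% c("chicken_min_id", "bird_min_id",
                                     "min_bidir_cov")]
  cls_args <- dots[names(dots) %in% c("misc_keywords", "min_orf_aa")]
  out <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cid <- names(candidates)[i]
    clen <- nchar(candidates[[i]])
    nth <- if (is.null(nt_hits)) empty_hits() else
      nt_hits[nt_hits$query_id == cid, , drop = FALSE]
    call_nt <- do.call(assign_name_nt,
                       c(list(cid, clen, nth), nt_args))
    name <- call_nt$name; tier <- "nt"; discordant <- call_nt$discordant
    if (is.na(name) && !is.null(prot_hits) && !is.null(accession_map)) {
      ph <- prot_hits[prot_hits$query_id == cid, , drop = FALSE]
      call_p <- assign_name_prot(cid, clen, ph, accession_map)
      name <- call_p$name; if (!is.na(name)) tier <- "protein"
    }
    orfs <- find_orfs(candidates[[i]], strand_specific = TRUE)
    longest <- if (nrow(orfs)) orfs$length_aa[1L] else 0L
    dom <- if (!is.null(domain_evidence) &&
               cid %in% domain_evidence$candidate_id)
      domain_evidence[domain_evidence$candidate_id == cid, ][1L, ] else
        list(has_domain = FALSE, has_signal_peptide = FALSE,
             has_tm_domain = FALSE)
    call <- do.call(classify_biotype, c(list(list(
      name = name, name_tier = tier, longest_orf_aa = longest,
      has_domain = isTRUE(dom$has_domain),
      has_signal_peptide = isTRUE(dom$has_signal_peptide),
      has_tm_domain = isTRUE(dom$has_tm_domain))), cls_args))
    out[[i]] <- data.frame(candidate_id = cid, name = call$name,
                           biotype = call$biotype,
                           evidence_tier = call$evidence_tier,
                           longest_orf_aa = longest,
                           discordant = discordant, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
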