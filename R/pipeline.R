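#' Run the full post-processing pipeline on a toy world
#'
#' End-to-end driver over the package's modules, at toy scale: quality
#' gate on the simulated reads; alignment of the de novo isoforms
#' (contigs) against the genome-guided gene candidates and contig
#' assignment by the novelty rule; consensus construction per candidate;
#' extraction of uncovered regions and assembly of the artificial
#' chromosome; the tiered naming + biotype cascade against the reference
#' transcript database; and strand-specific fragment counting of the
#' same simulated reads under two gene models — the genome-only
#' candidate model (what a reference annotation would offer) and the
#' model extended with the artificial chromosome.
#'
#' @param config a [toy_config()].
#' @param n_pairs number of simulated read pairs (default 400).
#' @param min_region minimum uncovered-region length carried to the
#'   artificial chromosome (default 400 bp).
#' @param spacer N-spacer of the artificial chromosome (default 250 bp).
#' @return list with the world, the intermediate products and the two
#'   `assignment_report`s (`report_reference`, `report_full`).
#' @export
run_toy_pipeline <- function(config, n_pairs = 400L, min_region = 400L,
                             spacer = 250L) {
  world <- make_toy_world(config)
  isoset <- world_isoforms(world, config)
  sim <- simulate_read_pairs(isoset, n_pairs, config)
  qc <- filter_pairs(sim$r1, sim$r2, min_median = 28)

  # --- contig assignment: de novo isoforms vs genome-guided candidates
  contig_hits <- toy_align(isoset$seqs, world$candidates)
  assign_list <- lapply(names(isoset$seqs), function(cid)
    assign_contig(cid, contig_hits[contig_hits$query_id == cid, , drop = FALSE]))
  assignments <- do.call(rbind, c(lapply(assign_list, `[[`, "assignments"),
                                  list(data.frame())))

  # --- consensus per candidate with assigned contigs
  by_cand <- split(assignments$contig_id, assignments$gene_candidate_id)
  consensus <- lapply(names(by_cand), function(cand)
    build_consensus(cand, isoset$seqs[by_cand[[cand]]]))
  names(consensus) <- names(by_cand)

  # --- novel regions -> artificial chromosome
  region_seqs <- character(); region_src <- list()
  for (cand in names(consensus)) {
    cseq <- consensus[[cand]]$sequence
    h <- toy_align(stats::setNames(cseq, cand),
                   world$candidates[cand])
    cov <- if (nrow(h) > 0L) coverage_union(h, "query") else
      structure(list(target_id = cand,
                     covered = data.frame(start = integer(), end = integer())),
                class = "coverage_map")
    reg <- uncovered_regions(nchar(cseq), cov, min_len = min_region,
                             target_seq = cseq)
    if (nrow(reg) > 0L) {
      for (r in seq_len(nrow(reg))) {
        rid <- sprintf("%s_region%d", cand, r)
        region_seqs[rid] <- substring(cseq, reg$start[r] + 1L, reg$end[r])
        region_src[[rid]] <- data.frame(candidate_id = cand,
                                        t_start = reg$start[r],
                                        t_end = reg$end[r],
                                        stringsAsFactors = FALSE)
      }
    }
  }
  chru <- NULL; chru_map <- NULL; chru_features <- NULL
  if (length(region_seqs) > 0L) {
    chru <- build_artificial_chromosome(region_seqs, spacer = spacer)
    src <- do.call(rbind, region_src[chru$features$candidate_id])
    chru_map <- data.frame(candidate_id = src$candidate_id,
                           t_start = src$t_start, t_end = src$t_end,
                           chru_start = chru$features$start,
                           chru_name = chru$name, stringsAsFactors = FALSE)
    chru_features <- data.frame(seqid = chru$name,
                                start = chru$features$start,
                                end = chru$features$end, strand = "+",
                                gene_id = src$candidate_id,
                                transcript_id = chru$features$candidate_id,
                                source = "dualtx", stringsAsFactors = FALSE)
  }

  # --- annotation of the consensus candidates
  ann_seqs <- world$candidates
  for (cand in names(consensus)) ann_seqs[cand] <- consensus[[cand]]$sequence
  ref_seqs <- stats::setNames(world$reference_db$seq, world$reference_db$ref_id)
  nt_hits <- toy_align(ann_seqs, ref_seqs)
  k <- match(nt_hits$subject_id, world$reference_db$ref_id)
  nt_hits$gene_name <- world$reference_db$gene_name[k]
  nt_hits$taxon <- world$reference_db$taxon[k]
  nt_hits$subject_len <- nchar(world$reference_db$seq)[k]
  annotation <- annotate_candidates(ann_seqs, nt_hits = nt_hits,
                                    domain_evidence = world$domain_evidence)

  # --- fragment counting under the two gene models
  feats_ref <- world$candidate_features
  feats_full <- if (is.null(chru_features)) feats_ref else
    rbind(feats_ref, chru_features)
  count_model <- function(chru_map_used, feats) {
    pairs <- project_read_pairs(sim, isoset, world, config,
                                chru_map = chru_map_used)
    sam <- tempfile(fileext = ".sam")
    lens <- c(nchar(world$genome),
              if (!is.null(chru) && !is.null(chru_map_used))
                stats::setNames(nchar(chru$sequence), chru$name))
    write_sam_min(pairs, sam, seq_lengths = lens)
    parsed <- read_sam_min(sam, default_read_len = config$read_length)
    unlink(sam)
    cf <- count_fragments(parsed$pairs, feats)
    list(pairs = pairs, counts = cf,
         report = summarize_assignment(cf$labels$label, cf$n_total))
  }
  ref_model <- count_model(NULL, feats_ref)
  full_model <- count_model(chru_map, feats_full)

  list(world = world, isoset = isoset, sim = sim, qc = qc,
       contig_hits = contig_hits, assignments = assignments,
       consensus = consensus, regions = region_seqs, chru = chru,
       chru_map = chru_map, annotation = annotation,
       counts_reference = ref_model$counts, counts_full = full_model$counts,
       report_reference = ref_model$report, report_full = full_model$report)
}
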