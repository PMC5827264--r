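#' Configuration of a toy transcriptome world
#'
#' The generator emulates the study design this toolkit targets: a
#' fragmented draft genome (ordered chromosomes plus unplaced contigs,
#' with part of the transcribed sequence missing from the assembly
#' altogether), multi-isoform genes, and strand-specific 50-bp paired-end
#' reads with a 150-bp insert (so one read pair spans 250 bp). Every
#' generator is a pure function of (config, seed).
#'
#' @param seed integer seed driving all randomness.
#' @param n_ordered_chromosomes,n_unplaced_contigs genome composition.
#' @param n_genes number of genes (>= 8 so that every biotype and
#'   fragmentation class is represented).
#' @param isoforms_per_gene inclusive range for the isoform count.
#' @param exon_length_range,intron_length_range bp ranges.
#' @param fraction_fragmented fraction of genes split across two
#'   sequences (cycled over the three fragmentation classes).
#' @param fraction_missing_from_genome fraction of genes with one
#'   internal exon absent from the genome (present only in transcripts);
#'   such hidden exons are drawn 420-550 bp so the novel region is
#'   recoverable by the 400-bp region filter.
#' @param n_noncoding,n_unnamed_coding,n_misc biotype composition: genes
#'   absent from the reference database without/with a long ORF, and
#'   genes named with a ribosomal-RNA keyword.
#' @param read_length,insert_size library geometry (bp).
#' @param low_quality_rate per-read probability of drawing the
#'   low-quality mixture component (Phred ~24 +- 2, versus ~38 +- 2),
#'   which puts the read's median below the quality gate.
#' @return list of class `toy_config`.
#' @export
toy_config <- function(seed = 1L, n_ordered_chromosomes = 2L,
                       n_unplaced_contigs = 4L, n_genes = 12L,
                       isoforms_per_gene = c(2L, 3L),
                       exon_length_range = c(200L, 400L),
                       intron_length_range = c(100L, 300L),
                       fraction_fragmented = 0.25,
                       fraction_missing_from_genome = 1 / 6,
                       n_noncoding = 3L, n_unnamed_coding = 2L, n_misc = 1L,
                       read_length = 50L, insert_size = 150L,
                       low_quality_rate = 0.05) {
  cfg <- list(seed = as.integer(seed),
              n_ordered_chromosomes = as.integer(n_ordered_chromosomes),
              n_unplaced_contigs = as.integer(n_unplaced_contigs),
              n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              exon_length_range = as.integer(exon_length_range),
              intron_length_range = as.integer(intron_length_range),
              fraction_fragmented = fraction_fragmented,
              fraction_missing_from_genome = fraction_missing_from_genome,
              n_noncoding = as.integer(n_noncoding),
              n_unnamed_coding = as.integer(n_unnamed_coding),
              n_misc = as.integer(n_misc),
              read_length = as.integer(read_length),
              insert_size = as.integer(insert_size),
              low_quality_rate = low_quality_rate)
  stopifnot(cfg$n_genes >= cfg$n_misc + cfg$n_noncoding + cfg$n_unnamed_coding,
            all(cfg$exon_length_range > 0L), all(cfg$intron_length_range > 0L),
            cfg$fraction_fragmented >= 0, cfg$fraction_fragmented <= 1,
            cfg$fraction_missing_from_genome >= 0,
            cfg$fraction_missing_from_genome <= 1)
  class(cfg) <- "toy_config"
  cfg
}

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1L, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

# random coding region: ATG + n_aa-1 sense codons + TAA (n_aa incl. start)
random_cds <- function(n_aa) {
  paste0("ATG", paste(sample(NON_STOP_CODONS, n_aa - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}

# Nudge internal exon boundaries (a few bp) so that consecutive exons
# never share their first or last base. Exact matches between an isoform
# and a consensus can then never slip across an exon junction, keeping
# block boundaries identifiable — the property the superTranscript
# equality oracle relies on.
adjust_exon_bounds <- function(seq, bounds) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(bounds)
  if (n < 3L) return(bounds)
  for (i in 2:(n - 1L)) {
    b <- bounds[i]; prev <- bounds[i - 1L]
    for (d in c(0L, 1L, -1L, 2L, -2L, 3L, -3L, 4L, -4L, 5L, -5L)) {
      bb <- b + d
      ok <- bb > prev + 20L && bb < bounds[i + 1L] - 20L &&
        ch[bb + 1L] != ch[prev + 1L] &&
        (prev == 0L || ch[bb] != ch[prev]) &&
        (i < n - 1L || ch[bb] != ch[bounds[n]])
      if (ok) { bounds[i] <- bb; break }
    }
  }
  bounds
}

# mutate a sequence until no forward-frame ORF reaches max_aa amino acids
enforce_short_orfs <- function(seq, max_aa = 99L) {
  for (iter in 1:100) {
    orfs <- find_orfs(seq, strand_specific = TRUE, min_aa = max_aa + 1L)
    if (nrow(orfs) == 0L) return(seq)
    o <- orfs[1L, ]
    mid <- o$start + 3L * (o$length_aa %/% 2L)  # in-frame internal codon
    substr(seq, mid + 1L, mid + 3L) <- "TAA"
  }
  stop("could not suppress long ORFs")  # nocov
}

#' Generate a deterministic toy world
#'
#' Builds the genome (ordered chromosomes + unplaced contigs), the true
#' gene models, the genome-guided gene-candidate stand-ins (transcript
#' sequence minus any hidden exon, with exon features on the genome), a
#' reference transcript database for the naming tier, domain evidence,
#' and a per-gene truth table.
#'
#' @param config a [toy_config()].
#' @return list of class `toy_world`; see the elements `genome`,
#'   `chrom_class`, `genes`, `candidates`, `candidate_features`,
#'   `reference_db`, `domain_evidence`, `gene_table`.
#' @export
make_toy_world <- function(config) {
  stopifnot(inherits(config, "toy_config"))
  with_seed(config$seed, make_toy_world_impl(config))
}

make_toy_world_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_ordered_chromosomes))
  contigs <- sprintf("contig_%03d", seq_len(cfg$n_unplaced_contigs))
  chrom_class <- stats::setNames(c(rep("ordered", length(chroms)),
                                   rep("unplaced", length(contigs))),
                                 c(chroms, contigs))
  n <- cfg$n_genes
  roles <- rep("protein_coding_named", n)
  i <- 1L
  if (cfg$n_misc > 0L) { roles[i:(i + cfg$n_misc - 1L)] <- "miscellaneous"; i <- i + cfg$n_misc }
  if (cfg$n_noncoding > 0L) { roles[i:(i + cfg$n_noncoding - 1L)] <- "ncRNA"; i <- i + cfg$n_noncoding }
  if (cfg$n_unnamed_coding > 0L) {
    half <- ceiling(cfg$n_unnamed_coding / 2)
    roles[i:(i + half - 1L)] <- "putative_protein"
    if (cfg$n_unnamed_coding > half)
      roles[(i + half):(i + cfg$n_unnamed_coding - 1L)] <- "uncharacterized_protein"
    i <- i + cfg$n_unnamed_coding
  }
  named_idx <- which(roles == "protein_coding_named")
  n_frag <- min(round(cfg$fraction_fragmented * n), length(named_idx))
  frag_idx <- named_idx[seq_len(n_frag)]
  frag_class <- rep(c("multi_ordered", "multi_unplaced", "mixed"),
                    length.out = n_frag)
  remaining <- setdiff(named_idx, frag_idx)
  n_hidden <- min(round(cfg$fraction_missing_from_genome * n), length(remaining))
  hidden_idx <- remaining[seq_len(n_hidden)]

  genes <- vector("list", n)
  seq_pool <- c(chroms, contigs)
  for (g in seq_len(n)) {
    gene_id <- sprintf("g%03d", g)
    role <- roles[g]
    strand <- sample(c("+", "-"), 1L)
    n_exons <- sample(4:6, 1L)
    elens <- sample(seq(cfg$exon_length_range[1L], cfg$exon_length_range[2L]),
                    n_exons, replace = TRUE)
    hidden_exon <- NA_integer_
    if (g %in% hidden_idx) {
      hidden_exon <- sample(2:(n_exons - 1L), 1L)
      elens[hidden_exon] <- sample(420:550, 1L)
    }
    tlen <- sum(elens)
    if (role %in% c("protein_coding_named", "putative_protein",
                    "uncharacterized_protein")) {
      n_aa <- sample(110:150, 1L)
      cds <- random_cds(n_aa)
      utr5_len <- sample(80:min(250L, tlen - nchar(cds) - 80L), 1L)
      transcript <- paste0(random_dna(utr5_len), cds,
                           random_dna(tlen - utr5_len - nchar(cds)))
    } else {
      transcript <- enforce_short_orfs(random_dna(tlen))
    }
    bounds <- adjust_exon_bounds(transcript, cumsum(c(0L, elens)))
    elens <- diff(bounds)
    exons <- data.frame(
      exon_idx = seq_len(n_exons),
      len = elens,
      t_start = bounds[-length(bounds)], t_end = bounds[-1L],
      seq = substring(transcript, bounds[-length(bounds)] + 1L, bounds[-1L]),
      hidden = !is.na(hidden_exon) & seq_len(n_exons) == hidden_exon,
      seqid = NA_character_, gstart = NA_integer_, gend = NA_integer_,
      stringsAsFactors = FALSE)
    if (g %in% frag_idx) {
      cls <- frag_class[match(g, frag_idx)]
      split_at <- n_exons %/% 2L
      seqs2 <- switch(cls,
                      multi_ordered = chroms[1:2],
                      multi_unplaced = contigs[1:2],
                      mixed = c(chroms[1L], contigs[min(3L, length(contigs))]))
      part_of <- ifelse(exons$exon_idx <= split_at, seqs2[1L], seqs2[2L])
    } else {
      cls <- "single_location"
      part_of <- rep(seq_pool[(g - 1L) %% length(seq_pool) + 1L], n_exons)
    }
    exons$seqid <- ifelse(exons$hidden, NA_character_, part_of)
    name <- switch(role,
                   miscellaneous = sprintf("RN18S%d-rRNA", g),
                   protein_coding_named = sprintf("TOYG%03d", g),
                   NA_character_)
    genes[[g]] <- list(gene_id = gene_id,
                       candidate_id = sprintf("cand%03d", g),
                       name = name, biotype = role, strand = strand,
                       exons = exons, transcript = transcript,
                       superTranscript = transcript,
                       fragmentation = cls,
                       has_domain = role == "putative_protein",
                       in_reference = !is.na(name))
  }

  # lay parts onto the genome; minus-strand genes are placed reversed and
  # reverse-complemented so transcription reads exon 1..n
  cursors <- stats::setNames(integer(length(seq_pool)), seq_pool)
  pieces <- stats::setNames(rep(list(character()), length(seq_pool)), seq_pool)
  for (g in seq_len(n)) {
    gene <- genes[[g]]
    placed <- gene$exons[!gene$exons$hidden, , drop = FALSE]
    for (sid in unique(placed$seqid)) {
      part <- placed[placed$seqid == sid, , drop = FALSE]
      ord <- if (gene$strand == "+") order(part$exon_idx) else
        order(-part$exon_idx)
      part <- part[ord, , drop = FALSE]
      spacer <- random_dna(400L)
      pieces[[sid]] <- c(pieces[[sid]], spacer)
      cur <- cursors[[sid]] + 400L
      for (j in seq_len(nrow(part))) {
        if (j > 1L) {
          intron <- random_dna(sample(seq(cfg$intron_length_range[1L],
                                          cfg$intron_length_range[2L]), 1L))
          pieces[[sid]] <- c(pieces[[sid]], intron)
          cur <- cur + nchar(intron)
        }
        eseq <- if (gene$strand == "+") part$seq[j] else revcomp(part$seq[j])
        pieces[[sid]] <- c(pieces[[sid]], eseq)
        k <- which(genes[[g]]$exons$exon_idx == part$exon_idx[j])
        genes[[g]]$exons$gstart[k] <- cur
        genes[[g]]$exons$gend[k] <- cur + nchar(eseq)
        cur <- cur + nchar(eseq)
      }
      cursors[[sid]] <- cur
    }
  }
  genome <- vapply(pieces, paste, character(1), collapse = "")
  genome <- genome[nchar(genome) > 0L | TRUE]  # keep empty contigs too
  empty <- nchar(genome) == 0L
  genome[empty] <- vapply(which(empty), function(i) random_dna(800L), "")

  candidates <- character(n)
  feat <- list()
  for (g in seq_len(n)) {
    gene <- genes[[g]]
    placed <- gene$exons[!gene$exons$hidden, , drop = FALSE]
    candidates[g] <- paste(placed$seq[order(placed$exon_idx)], collapse = "")
    feat[[g]] <- data.frame(seqid = placed$seqid, start = placed$gstart,
                            end = placed$gend, strand = gene$strand,
                            gene_id = gene$candidate_id,
                            transcript_id = gene$candidate_id,
                            source = "toy", stringsAsFactors = FALSE)
    # candidate-sequence offset of each placed exon
    off <- cumsum(c(0L, placed$len[order(placed$exon_idx)]))
    genes[[g]]$exons$c_start <- NA_integer_
    genes[[g]]$exons$c_start[match(placed$exon_idx[order(placed$exon_idx)],
                                   genes[[g]]$exons$exon_idx)] <-
      off[-length(off)]
  }
  names(candidates) <- vapply(genes, `[[`, "", "candidate_id")

  in_ref <- vapply(genes, `[[`, logical(1), "in_reference")
  reference_db <- data.frame(
    ref_id = sprintf("ref_%s", vapply(genes[in_ref], `[[`, "", "gene_id")),
    gene_name = vapply(genes[in_ref], `[[`, "", "name"),
    taxon = "chicken",
    seq = vapply(genes[in_ref], `[[`, "", "superTranscript"),
    stringsAsFactors = FALSE)

  gene_table <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    candidate_id = vapply(genes, `[[`, "", "candidate_id"),
    name = vapply(genes, `[[`, "", "name"),
    biotype = vapply(genes, `[[`, "", "biotype"),
    strand = vapply(genes, `[[`, "", "strand"),
    fragmentation = vapply(genes, `[[`, "", "fragmentation"),
    has_hidden_exon = vapply(genes, function(x) any(x$exons$hidden), logical(1)),
    stringsAsFactors = FALSE)

  structure(list(
    config = NULL, genome = genome, chrom_class = chrom_class,
    genes = stats::setNames(genes, gene_table$gene_id),
    candidates = candidates,
    candidate_features = do.call(rbind, feat),
    reference_db = reference_db,
    domain_evidence = data.frame(
      candidate_id = gene_table$candidate_id,
      has_domain = vapply(genes, `[[`, logical(1), "has_domain"),
      has_signal_peptide = FALSE, has_tm_domain = FALSE,
      stringsAsFactors = FALSE),
    gene_table = gene_table), class = "toy_world")
}

#' @export
print.toy_world <- function(x, ...) {
  cat("<toy_world> ", length(x$genes), " genes on ",
      length(x$genome), " sequences (",
      sum(x$chrom_class == "ordered"), " ordered, ",
      sum(x$chrom_class == "unplaced"), " unplaced)\n", sep = "")
  invisible(x)
}

#' Generate isoforms of one toy gene
#'
#' Isoforms are exon-block subsets of the gene's exon chain: each
#' non-seed isoform skips one internal exon, with skipped positions at
#' least two exons apart (so relative block order stays decidable from
#' pairwise ungapped comparisons) and hidden exons never skipped. The
#' union of the isoforms always contains every exon, making the full
#' exon concatenation the true superTranscript.
#'
#' @param gene one element of `toy_world$genes`.
#' @param k number of isoforms.
#' @param seed integer seed.
#' @return list with `seqs` (named character vector) and `segments`
#'   (data.frame: `transcript_id`, `exon_idx`, `iso_start`, `iso_end`).
#' @export
make_isoforms <- function(gene, k, seed) {
  with_seed(seed, {
    n <- nrow(gene$exons)
    skippable <- setdiff(2:(n - 1L), which(gene$exons$hidden))
    skips <- integer()
    if (k > 1L && length(skippable) > 0L) {
      pool <- skippable
      while (length(skips) < k && length(pool) > 0L) {
        s <- pool[sample.int(length(pool), 1L)]
        skips <- c(skips, s)
        pool <- pool[abs(pool - s) >= 2L]
      }
    }
    seqs <- character(k); segs <- vector("list", k)
    for (j in seq_len(k)) {
      keep <- seq_len(n)
      if (j <= length(skips)) keep <- setdiff(keep, skips[j])
      ex <- gene$exons[keep, , drop = FALSE]
      tid <- sprintf("%s_i%d", gene$gene_id, j)
      seqs[j] <- paste(ex$seq, collapse = "")
      off <- cumsum(c(0L, ex$len))
      segs[[j]] <- data.frame(transcript_id = tid, exon_idx = ex$exon_idx,
                              iso_start = off[-length(off)], iso_end = off[-1L],
                              stringsAsFactors = FALSE)
      names(seqs)[j] <- tid
    }
    list(seqs = seqs, segments = do.call(rbind, segs))
  })
}

#' Generate isoform sets for every gene of a toy world
#'
#' @param world a `toy_world`.
#' @param config the [toy_config()] used to build it.
#' @return list with `seqs` (named vector over all isoforms), `segments`
#'   (combined segment table) and `gene_of` (named vector isoform ->
#'   gene_id).
#' @export
world_isoforms <- function(world, config) {
  ks <- with_seed(config$seed + 1L,
                  sample(seq(config$isoforms_per_gene[1L],
                             config$isoforms_per_gene[2L]),
                         length(world$genes), replace = TRUE))
  out <- lapply(seq_along(world$genes), function(i)
    make_isoforms(world$genes[[i]], ks[i], seed = config$seed + 100L + i))
  seqs <- unlist(lapply(out, `[[`, "seqs"))
  segments <- do.call(rbind, lapply(out, `[[`, "segments"))
  gene_of <- stats::setNames(sub("_i\\d+$", "", names(seqs)), names(seqs))
  list(seqs = seqs, segments = segments, gene_of = gene_of)
}

#' Simulate stranded 50-bp paired-end read pairs from transcripts
#'
#' Fragments are placed uniformly along transcripts, with the insert
#' fixed at its mean so each fragment spans exactly
#' `2 * read_length + insert_size` bases. Orientation is fr-firststrand:
#' the first-in-pair read is the reverse complement of the transcript
#' strand. Base qualities are drawn from a two-component mixture
#' (Phred ~38 +- 2 versus ~24 +- 2 with probability `low_quality_rate`),
#' so the median-quality gate has work to do on both sides.
#'
#' @param isoset isoform set from [world_isoforms()] (or any list with
#'   `seqs` and `gene_of`).
#' @param n_pairs number of pairs.
#' @param config a [toy_config()].
#' @param seed integer seed (defaults to `config$seed + 2`).
#' @return list with `r1`, `r2` (`fastq_reads`) and `truth` (data.frame:
#'   `pair_id`, `transcript_id`, `gene_id`, `frag_start`, `low1`, `low2`).
#' @export
simulate_read_pairs <- function(isoset, n_pairs, config,
                                seed = config$seed + 2L) {
  rl <- config$read_length
  span <- 2L * rl + config$insert_size
  lens <- nchar(isoset$seqs)
  ok <- lens >= span
  stopifnot(any(ok))
  with_seed(seed, {
    tid <- sample(names(isoset$seqs)[ok], n_pairs, replace = TRUE)
    fs <- vapply(lens[tid] - span, function(m) sample.int(m + 1L, 1L) - 1L,
                 integer(1))
    sense <- substring(isoset$seqs[tid], fs + 1L, fs + rl)
    anti <- vapply(substring(isoset$seqs[tid], fs + span - rl + 1L, fs + span),
                   revcomp, character(1))
    low1 <- stats::runif(n_pairs) < config$low_quality_rate
    low2 <- stats::runif(n_pairs) < config$low_quality_rate
    qual_vec <- function(low) {
      mu <- if (low) 24 else 38
      pmin(40L, pmax(2L, as.integer(round(stats::rnorm(rl, mu, 2)))))
    }
    ids <- sprintf("pair%05d", seq_len(n_pairs))
    r1 <- fastq_reads(ids, unname(anti), lapply(low1, qual_vec))
    r2 <- fastq_reads(ids, unname(sense), lapply(low2, qual_vec))
    list(r1 = r1, r2 = r2,
         truth = data.frame(pair_id = ids, transcript_id = unname(tid),
                            gene_id = unname(isoset$gene_of[tid]),
                            frag_start = fs, low1 = low1, low2 = low2,
                            stringsAsFactors = FALSE))
  })
}

#' Alignment-free projection of simulated pairs into SAM-style records
#'
#' Converts the simulator's truth (transcript + fragment position) into
#' mapped paired records against a given gene model, standing in for the
#' spliced aligner at toy scale. A mate maps when its 50 bp fall entirely
#' within one exon block of its isoform: placed exons project to genomic
#' coordinates (strand-aware), hidden exons project onto the artificial
#' chromosome when `chru_map` provides the corresponding block, and
#' everything else (junction-spanning mates, hidden sequence without a
#' model) is emitted unmapped.
#'
#' @param sim output of [simulate_read_pairs()].
#' @param isoset the isoform set the reads were simulated from.
#' @param world the `toy_world`.
#' @param config the [toy_config()].
#' @param chru_map optional data.frame (`candidate_id`, `t_start`,
#'   `t_end`, `chru_start`, `chru_name`): which superTranscript interval
#'   of which candidate sits where on the artificial chromosome.
#' @return data.frame of paired records in the layout of
#'   `read_sam_min()$pairs`, plus a `junction1`/`junction2` truth column
#'   marking mates that span exon junctions.
#' @export
project_read_pairs <- function(sim, isoset, world, config, chru_map = NULL) {
  rl <- config$read_length
  span <- 2L * rl + config$insert_size
  segs <- split(isoset$segments, isoset$segments$transcript_id)
  n <- nrow(sim$truth)
  res <- data.frame(query_name = sim$truth$pair_id,
                    flag1 = NA_integer_, flag2 = NA_integer_,
                    ref1 = "*", ref2 = "*", pos1 = 0L, pos2 = 0L,
                    mapq1 = 60L, mapq2 = 60L, span1 = rl, span2 = rl,
                    junction1 = FALSE, junction2 = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tr <- sim$truth[i, ]
    gene <- world$genes[[tr$gene_id]]
    sg <- segs[[tr$transcript_id]]
    locate <- function(a) {  # a: 0-based mate start on the isoform
      hit <- which(sg$iso_start <= a & a + rl <= sg$iso_end)
      if (length(hit) == 0L)
        return(list(ref = "*", pos = 0L, fwd = NA, junction = TRUE))
      e <- gene$exons[gene$exons$exon_idx == sg$exon_idx[hit[1L]], ]
      off <- a - sg$iso_start[hit[1L]]
      if (!e$hidden) {
        if (gene$strand == "+") {
          list(ref = e$seqid, pos = e$gstart + off + 1L, fwd = TRUE,
               junction = FALSE)
        } else {
          list(ref = e$seqid, pos = e$gend - off - rl + 1L, fwd = FALSE,
               junction = FALSE)
        }
      } else {
        tpos <- e$t_start + off
        if (!is.null(chru_map)) {
          m <- chru_map[chru_map$candidate_id == gene$candidate_id &
                          chru_map$t_start <= tpos &
                          tpos + rl <= chru_map$t_end, , drop = FALSE]
          if (nrow(m) > 0L)
            return(list(ref = m$chru_name[1L],
                        pos = m$chru_start[1L] + (tpos - m$t_start[1L]) + 1L,
                        fwd = TRUE, junction = FALSE))
        }
        list(ref = "*", pos = 0L, fwd = NA, junction = FALSE)
      }
    }
    l2 <- locate(tr$frag_start)                  # sense mate (second in pair)
    l1 <- locate(tr$frag_start + span - rl)      # antisense mate (first)
    # orientation on the reference: sense mate forward iff + placement
    f1 <- 1L + 64L; f2 <- 1L + 128L
    m1 <- l1$ref != "*"; m2 <- l2$ref != "*"
    if (m1) { if (isTRUE(l1$fwd)) f1 <- f1 + 16L } else f1 <- f1 + 4L
    if (m2) { if (!isTRUE(l2$fwd)) f2 <- f2 + 16L } else f2 <- f2 + 4L
    # note: first-in-pair is antisense, so it is reverse when the
    # transcript lies forward on the reference
    if (m1 && m2) {
      if (bitwAnd(f1, 16L) > 0L) f2 <- f2 + 32L
      if (bitwAnd(f2, 16L) > 0L) f1 <- f1 + 32L
      if (l1$ref == l2$ref) { f1 <- f1 + 2L; f2 <- f2 + 2L }
    } else {
      if (!m1) f2 <- f2 + 8L
      if (!m2) f1 <- f1 + 8L
    }
    res$flag1[i] <- f1; res$flag2[i] <- f2
    res$ref1[i] <- l1$ref; res$ref2[i] <- l2$ref
    res$pos1[i] <- l1$pos; res$pos2[i] <- l2$pos
    res$junction1[i] <- l1$junction; res$junction2[i] <- l2$junction
  }
  res
}

#' Toy exhaustive ungapped aligner
#'
#' Seed-and-extend exhaustive ungapped local alignment over all
#' query/subject pairs, reported as 12-column tabular hits with exact
#' identities and coordinates — the in-package oracle standing in for
#' the external aligner on sequences up to ~10 kb. Plus-strand only by
#' default, matching how the pipeline's nucleotide comparisons are run.
#'
#' @param queries,subjects named character vectors.
#' @param min_identity minimum percent identity of a reported hit.
#' @param min_len minimum hit length (default 20).
#' @param plus_only search the plus strand only (default `TRUE`).
#' @return a `hits_tab` data.frame (see [read_hits_tab()]).
#' @export
toy_align <- function(queries, subjects, min_identity = 90, min_len = 20L,
                      plus_only = TRUE) {
  stopifnot(!is.null(names(queries)), !is.null(names(subjects)))
  rows <- list()
  emit <- function(qid, sid, m, strand, nq) {
    if (nrow(m) == 0L) return()
    if (strand == "-") {
      qs <- nq - m$x_end + 1L; qe <- nq - m$x_start
    } else {
      qs <- m$x_start + 1L; qe <- m$x_end
    }
    mm <- m$length - m$matches
    rows[[length(rows) + 1L]] <<- data.frame(
      query_id = qid, subject_id = sid,
      pct_identity = round(m$pct_identity, 2), aln_length = m$length,
      mismatches = mm, gap_open = 0L,
      q_start = qs, q_end = qe,
      s_start = m$y_start + 1L, s_end = m$y_end,
      s_strand = strand,
      evalue = signif(2^(-pmin(1000, 2 * m$matches - 3 * mm)), 3),
      bitscore = 2 * m$matches - 3 * mm,
      stringsAsFactors = FALSE)
  }
  k <- max(1L, min(12L, as.integer(min_len)))
  qk <- lapply(queries, seq_kmers, k = k)
  sidx <- lapply(subjects, kmer_index, k = k)
  qrc <- if (plus_only) NULL else vapply(queries, revcomp, character(1))
  qkrc <- if (plus_only) NULL else lapply(qrc, seq_kmers, k = k)
  for (qid in names(queries)) {
    for (sid in names(subjects)) {
      m <- ungapped_matches(queries[[qid]], subjects[[sid]],
                            min_identity = min_identity, min_len = min_len,
                            k = k, x_kmers = qk[[qid]], y_index = sidx[[sid]])
      emit(qid, sid, m, "+", nchar(queries[[qid]]))
      if (!plus_only) {
        mr <- ungapped_matches(qrc[[qid]], subjects[[sid]],
                               min_identity = min_identity, min_len = min_len,
                               k = k, x_kmers = qkrc[[qid]],
                               y_index = sidx[[sid]])
        emit(qid, sid, mr, "-", nchar(queries[[qid]]))
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  h <- do.call(rbind, rows)
  h <- h[order(h$query_id, -h$bitscore, h$subject_id), , drop = FALSE]
  rownames(h) <- NULL
  normalize_hits(h)
}
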