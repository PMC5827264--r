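test_that("shared blocks match the exhaustive exact-match oracle", {
  cons <- "AAAACCCCGGGG"
  iso <- "CCCC"
  b <- shared_blocks(cons, iso, min_block = 4L)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$cons_start, b$cons_end), c(4L, 8L))
  expect_equal(c(b$iso_start, b$iso_end), c(0L, 4L))
  oracle <- oracle_exact_blocks(cons, iso, min_len = 4L)
  expect_true(any(oracle$a_start == 4L & oracle$a_end == 8L &
                    oracle$b_start == 0L & oracle$b_end == 4L))

  set.seed(71)
  x <- rand_dna(600)
  b2 <- shared_blocks(x, x)
  expect_equal(nrow(b2), 1L)
  expect_equal(c(b2$cons_start, b2$cons_end, b2$iso_start, b2$iso_end),
               c(0L, 600L, 0L, 600L))
  expect_equal(b2$pct_identity, 100)

  # plus strand only: a reverse complement shares no blocks
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_equal(nrow(shared_blocks(x, rc)), 0L)
})

test_that("shared blocks agree with the oracle on random exon mosaics", {
  set.seed(72)
  for (i in 1:10) {
    exons <- replicate(4, rand_dna(sample(60:150, 1L)))
    cons <- paste(exons[c(1, 2, 4)], collapse = "")
    iso <- paste(exons[c(1, 3, 4)], collapse = "")
    b <- shared_blocks(cons, iso, min_block = 30L)
    # every reported block is an exact match present in the oracle set
    oracle <- oracle_exact_blocks(cons, iso, min_len = 30L)
    for (j in seq_len(nrow(b))) {
      expect_identical(substring(cons, b$cons_start[j] + 1L, b$cons_end[j]),
                       substring(iso, b$iso_start[j] + 1L, b$iso_end[j]))
      expect_true(any(oracle$a_start <= b$cons_start[j] &
                        oracle$a_end >= b$cons_end[j]))
    }
    # blocks never overlap on either sequence
    if (nrow(b) > 1L) {
      expect_true(all(b$cons_start[-1L] >= b$cons_end[-nrow(b)]))
      bi <- b[order(b$iso_start), ]
      expect_true(all(bi$iso_start[-1L] >= bi$iso_end[-nrow(b)]))
    }
  }
})

test_that("merging inserts isoform-unique segments at their block-adjacent positions", {
  A <- strrep("A", 30); B <- strrep("T", 30); C <- strrep("G", 30)
  skip_ab <- paste0(A, C)
  full <- paste0(A, B, C)
  cons <- consensus_init("cand", "i2", skip_ab)
  blocks <- shared_blocks(skip_ab, full, min_block = 10L)
  merged <- merge_isoform(cons, "i1", full, blocks)
  expect_equal(merged$sequence, full)

  # isoform entirely covered by blocks: sequence unchanged, support logged
  cons2 <- consensus_init("cand", "i1", full)
  b2 <- shared_blocks(full, skip_ab, min_block = 10L)
  merged2 <- merge_isoform(cons2, "i2", skip_ab, b2)
  expect_equal(merged2$sequence, full)
  expect_true("i2" %in% merged2$support$isoform_id)

  # an isoform with no shared block is appended, never dropped
  set.seed(73)
  lone <- rand_dna(80)
  merged3 <- merge_isoform(consensus_init("cand", "i1", full), "i9", lone,
                           shared_blocks(full, lone, min_block = 20L))
  expect_equal(merged3$sequence, paste0(full, lone))
})

test_that("consensus construction reproduces the exon-block superTranscript", {
  i1 <- "AAAATTTTGGGG"; i2 <- "AAAAGGGG"
  cons <- build_consensus("cand", c(i1 = i1, i2 = i2), min_block = 4L)
  expect_equal(cons$sequence, i1)

  single <- build_consensus("cand", c(only = "ACGTACGTAA"), min_block = 4L)
  expect_equal(single$sequence, "ACGTACGTAA")

  # three isoforms sharing a core with two distinct first exons:
  # the core appears once and both first exons are retained
  set.seed(74)
  core <- rand_dna(500); e5a <- rand_dna(120); e5b <- rand_dna(90)
  cons3 <- build_consensus("cand", c(a = paste0(e5a, core),
                                     b = paste0(e5b, core),
                                     c = core))
  expect_equal(nchar(cons3$sequence), 500L + 120L + 90L)
  expect_true(grepl(core, cons3$sequence, fixed = TRUE))
  expect_true(grepl(e5a, cons3$sequence, fixed = TRUE))
  expect_true(grepl(e5b, cons3$sequence, fixed = TRUE))
})

test_that("toy-gene consensus equals the superTranscript and bounds its inputs", {
  for (seed in c(3, 9, 15)) {
    cfg <- toy_config(seed = seed, n_genes = 8L)
    world <- make_toy_world(cfg)
    isoset <- world_isoforms(world, cfg)
    for (g in names(world$genes)) {
      iso <- isoset$seqs[isoset$gene_of == g]
      cons <- build_consensus(g, iso)
      st <- paste(world$genes[[g]]$exons$seq, collapse = "")
      expect_identical(cons$sequence, st)
      expect_lte(nchar(cons$sequence), sum(nchar(iso)))
      expect_gte(nchar(cons$sequence), max(nchar(iso)))
      # every isoform is recoverable as an ordered colinear chain of
      # consensus blocks covering it completely
      for (tid in names(iso)) {
        b <- shared_blocks(cons$sequence, iso[[tid]])
        b <- b[order(b$iso_start), ]
        expect_equal(sum(b$iso_end - b$iso_start), nchar(iso[[tid]]))
        expect_true(all(diff(b$cons_start) > 0))
      }
      # provenance tiles the consensus without overlap, all isoforms present
      prov <- consensus_provenance(cons)
      expect_equal(prov$cons_start, c(0L, utils::head(prov$cons_end, -1L)))
      expect_equal(prov$cons_end[nrow(prov)], nchar(cons$sequence))
      expect_setequal(unique(cons$support$isoform_id), names(iso))
      # folding the consensus into itself is a no-op on the sequence
      again <- build_consensus(g, c(stats::setNames(cons$sequence, "cons0"), iso))
      expect_identical(again$sequence, cons$sequence)
    }
  }
})

test_that("artificial chromosome layout follows the spacer arithmetic", {
  set.seed(75)
  seqs <- stats::setNames(vapply(c(500L, 600L, 700L), rand_dna, ""),
                          c("cA", "cB", "cC"))
  chrom <- build_artificial_chromosome(seqs, spacer = 250L)
  expect_equal(nchar(chrom$sequence), 2300L)          # 1800 + 2 spacers
  expect_equal(chrom$features$start, c(0L, 750L, 1600L))
  expect_equal(chrom$features$end, c(500L, 1350L, 2300L))
  # the second feature occupies exactly (750, 1350)
  expect_identical(substring(chrom$sequence, 751L, 1350L), unname(seqs[2L]))

  one <- build_artificial_chromosome(seqs[1L], spacer = 250L)
  expect_equal(nchar(one$sequence), 500L)
  zero <- build_artificial_chromosome(seqs, spacer = 0L)
  expect_equal(zero$sequence, paste(seqs, collapse = ""))
  expect_error(build_artificial_chromosome(c(a = "ACGT", b = "")), "empty")
})

test_that("artificial chromosome round-trips through FASTA/GTF with N spacers", {
  set.seed(76)
  seqs <- stats::setNames(vapply(c(420L, 510L), rand_dna, ""), c("r1", "r2"))
  chrom <- build_artificial_chromosome(seqs, spacer = 250L)
  fa <- withr::local_tempfile(fileext = ".fa")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_artificial_chromosome(chrom, fa, gtf)
  genome <- unname(read_fasta(fa)[chrom$name])
  feats <- read_gtf(gtf)
  for (i in seq_len(nrow(feats))) {
    expect_identical(substring(genome, feats$start[i] + 1L, feats$end[i]),
                     unname(seqs[feats$gene_id[i]]))
  }
  inter <- substring(genome, feats$end[1L] + 1L, feats$start[2L])
  expect_equal(nchar(inter), 250L)
  expect_identical(unique(strsplit(inter, "")[[1L]]), "N")
})
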