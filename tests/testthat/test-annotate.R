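test_that("bidirectional coverage is the per-axis union percentage", {
  h <- mk_hits("cand", "ref", qs = c(1L, 301L), qe = c(300L, 600L),
               ss = c(1L, 401L), se = c(250L, 700L))
  expect_equal(unname(bidirectional_coverage(1000L, 1000L, h)), c(60, 55))
  expect_equal(unname(bidirectional_coverage(1000L, 1000L, h[0, ])), c(0, 0))
  full <- mk_hits("cand", "ref", qs = 1L, qe = 1000L, ss = 1L, se = 1000L)
  expect_equal(unname(bidirectional_coverage(1000L, 1000L, full)), c(100, 100))
})

nt_hit <- function(identity, taxon = "chicken", name = "COL26A1",
                   qs = 1L, qe = 800L, ss = 1L, se = 800L, bitscore = 500) {
  mk_hits("cand", paste0("ref_", name), qs = qs, qe = qe, ss = ss, se = se,
          identity = identity, bitscore = bitscore,
          gene_name = name, taxon = taxon, subject_len = 1000L)
}

test_that("nucleotide naming honours the strict-chicken / inclusive-bird asymmetry", {
  # chicken hit at 95% identity with 80/80 coverage is assigned
  got <- assign_name_nt("cand", 1000L, nt_hit(95))
  expect_equal(got$name, "COL26A1")
  expect_false(got$discordant)
  # identity exactly 90 never qualifies for chicken ...
  expect_true(is.na(assign_name_nt("cand", 1000L, nt_hit(90))$name))
  expect_false(is.na(assign_name_nt("cand", 1000L, nt_hit(90.1))$name))
  # ... while 75 exactly qualifies for another bird
  expect_equal(assign_name_nt("cand", 1000L,
                              nt_hit(75, taxon = "other_bird"))$name, "COL26A1")
  expect_true(is.na(assign_name_nt("cand", 1000L,
                                   nt_hit(74.9, taxon = "other_bird"))$name))
  # bidirectional coverage must reach 50% on both axes
  low_q <- nt_hit(95, qs = 1L, qe = 450L)            # 45% of the candidate
  expect_true(is.na(assign_name_nt("cand", 1000L, low_q)$name))
  low_s <- nt_hit(95, ss = 1L, se = 450L)            # 45% of the subject
  expect_true(is.na(assign_name_nt("cand", 1000L, low_s)$name))
})

test_that("several qualifying names raise the discordance flag for manual review", {
  h <- rbind(nt_hit(95, name = "FLNA", bitscore = 700),
             nt_hit(95, name = "WNT11", bitscore = 400))
  got <- assign_name_nt("cand", 1000L, h)
  expect_true(got$discordant)
  expect_equal(got$name, "FLNA")  # best total bitscore still reported
  expect_setequal(got$qualifying, c("FLNA", "WNT11"))
})

test_that("protein naming applies homology and coverage floors through the accession map", {
  amap <- data.frame(accession = c("NP_001", "XP_002"),
                     gene_name = c("Wnt11", "Fgf8"), stringsAsFactors = FALSE)
  ph <- function(hom, qs = 1L, qe = 700L, acc = "NP_001")
    mk_hits("cand", acc, qs = qs, qe = qe, ss = 1L, se = 200L,
            pct_homology = hom)
  expect_equal(assign_name_prot("cand", 1000L, ph(45), amap)$name, "Wnt11")
  expect_equal(assign_name_prot("cand", 1000L, ph(30), amap)$name, "Wnt11")
  expect_true(is.na(assign_name_prot("cand", 1000L, ph(29.9), amap)$name))
  expect_true(is.na(assign_name_prot("cand", 1000L, ph(45, qe = 400L),
                                     amap)$name))
  expect_warning(
    res <- assign_name_prot("cand", 1000L, ph(45, acc = "ZZ_999"), amap),
    "unmapped")
  expect_true(is.na(res$name))
})

test_that("ORF finding agrees with the brute-force three-frame oracle", {
  set.seed(81)
  # embedded complete ORF: ATG + 99 sense codons + TAA -> 100 aa
  orf <- paste0("ATG", paste(sample(setdiff_codons(), 99L, TRUE),
                             collapse = ""), "TAA")
  seq <- paste0("TTAATTAA", orf, "TAGTAGTAG")
  got <- find_orfs(seq)
  expect_equal(got$length_aa[1L], 100L)
  expect_equal(got$completeness[1L], "complete")
  expect_identical(substring(seq, got$start[1L] + 1L, got$start[1L] + 3L), "ATG")

  # stop-only sequence yields nothing of length >= 1
  expect_equal(nrow(find_orfs(strrep("TAA", 40L))), 0L)

  # strand-specific scan ignores the reverse complement
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  got_rc <- find_orfs(rc, strand_specific = TRUE)
  expect_true(nrow(got_rc) == 0L || max(got_rc$length_aa) < 100L)
  got_both <- find_orfs(rc, strand_specific = FALSE)
  expect_equal(max(got_both$length_aa), 100L)

  for (i in 1:15) {
    s <- rand_dna(sample(1000:3000, 1L))
    got <- find_orfs(s)
    want <- oracle_orfs(s)
    key <- function(d) sort(sprintf("%d:%d:%d:%s", d$frame, d$start,
                                    d$length_aa, d$completeness))
    expect_identical(key(got), key(want))
  }
})

test_that("the biotype cascade is total and fires in the documented order", {
  ev <- function(name = NA, orf = 0L, dom = FALSE, sig = FALSE, tm = FALSE)
    list(name = name, name_tier = "nt", longest_orf_aa = orf,
         has_domain = dom, has_signal_peptide = sig, has_tm_domain = tm)
  expect_equal(classify_biotype(ev("TOYG1", orf = 150L))$biotype,
               "protein_coding_named")
  expect_equal(classify_biotype(ev("RN18S-like rRNA"))$biotype, "miscellaneous")
  expect_equal(classify_biotype(ev("SNRPA-pseudogene"))$biotype, "miscellaneous")
  expect_equal(classify_biotype(ev(orf = 150L, dom = TRUE))$biotype,
               "putative_protein")
  expect_equal(classify_biotype(ev(orf = 150L, sig = TRUE))$biotype,
               "putative_protein")
  expect_equal(classify_biotype(ev(orf = 150L))$biotype,
               "uncharacterized_protein")
  expect_equal(classify_biotype(ev(orf = 100L))$biotype,
               "uncharacterized_protein")  # exactly 100 aa reaches the tier
  expect_equal(classify_biotype(ev(orf = 99L))$biotype, "ncRNA")

  set.seed(82)
  biotypes <- replicate(60, classify_biotype(ev(
    name = sample(c(NA, "TOYG2", "RNA18S rRNA"), 1L),
    orf = sample(c(40L, 99L, 100L, 200L), 1L),
    dom = sample(c(TRUE, FALSE), 1L)))$biotype)
  expect_true(all(biotypes %in% c("protein_coding_named", "miscellaneous",
                                  "putative_protein",
                                  "uncharacterized_protein", "ncRNA")))
})

test_that("reference coverage bins distinguish undetected candidates", {
  h <- mk_hits("cand", "ref", qs = 1L, qe = 600L, ss = 1L, se = 600L)
  expect_equal(coverage_vs_reference(1000L, h),
               list(pct_covered = 60, bin = "at_least_50"))
  expect_equal(coverage_vs_reference(1000L, h[0, ]),
               list(pct_covered = 0, bin = "zero"))
  h499 <- mk_hits("cand", "ref", qs = 1L, qe = 499L, ss = 1L, se = 499L)
  expect_equal(coverage_vs_reference(1000L, h499),
               list(pct_covered = 49.9, bin = "below_50"))
})

test_that("name concordance classifies against covered reference hits only", {
  rh <- function(name, qe = 700L, bitscore = 400)
    mk_hits("cand", "refseq1", qs = 1L, qe = qe, ss = 1L, se = qe,
            bitscore = bitscore, gene_name = name)
  expect_equal(name_concordance("FLNA", 1000L, rh("FLNA")), "concordant")
  expect_equal(name_concordance("flna", 1000L, rh("FLNA")), "concordant")
  expect_equal(name_concordance("FLNA", 1000L, rh("WNT11")), "discordant")
  expect_equal(name_concordance("FLNA", 1000L, rh("FLNA", qe = 400L)),
               "no_match")
  expect_equal(name_concordance("FLNA", 1000L, rh(NA_character_)),
               "matched_undefined")
  syn <- data.frame(name = "FLN1", canonical = "FLNA")
  expect_equal(name_concordance("FLN1", 1000L, rh("FLNA"), synonyms = syn),
               "concordant")
})

test_that("biotype calls are independent of hit input order", {
  set.seed(83)
  h <- rbind(nt_hit(95, name = "FLNA", bitscore = 700),
             nt_hit(92, name = "FLNA", bitscore = 300),
             nt_hit(95, name = "WNT11", bitscore = 400))
  base <- assign_name_nt("cand", 1000L, h)
  for (i in 1:5) {
    perm <- h[sample(nrow(h)), , drop = FALSE]
    expect_equal(assign_name_nt("cand", 1000L, perm), base)
  }
})
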