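test_that("coverage union matches the per-base oracle", {
  h <- mk_hits("c1", "g1", qs = c(1L, 50L), qe = c(100L, 120L),
               ss = c(1L, 1L), se = c(100L, 71L))
  cov <- coverage_union(h, "query")
  expect_equal(cov$covered, data.frame(start = 0L, end = 120L))

  h2 <- mk_hits("c1", "g1", qs = c(1L, 21L), qe = c(10L, 30L),
                ss = c(1L, 1L), se = c(10L, 10L))
  expect_equal(coverage_union(h2, "query")$covered,
               data.frame(start = c(0L, 20L), end = c(10L, 30L)))
  expect_equal(nrow(coverage_union(empty_hits_for_test(), "query")$covered), 0L)

  set.seed(31)
  for (i in 1:25) {
    n <- sample(1:8, 1L)
    qs <- sample(1:400, n, replace = TRUE)
    qe <- pmin(500L, qs + sample(1:120, n, replace = TRUE))
    h <- mk_hits("c1", "g1", qs = qs, qe = qe, ss = qs, se = qe)
    cov <- coverage_union(h, "query")$covered
    oracle <- oracle_cover_bases(qs - 1L, qe, 500L)
    got <- oracle_cover_bases(cov$start, cov$end, 500L)
    expect_identical(got, oracle)
  }
  mixed <- mk_hits(c("c1", "c2"), "g1", qs = 1L, qe = 10L, ss = 1L, se = 10L)
  expect_error(coverage_union(mixed, "query"), "mix")
})

test_that("contig assignment enforces strict identity and inclusive novelty bounds", {
  # second hit contributes only 20 novel bases -> rejected
  h <- mk_hits("c1", c("gA", "gB"), qs = c(1L, 51L), qe = c(100L, 120L),
               ss = c(1L, 1L), se = c(100L, 70L), identity = 95,
               bitscore = c(200, 100))
  res <- assign_contig("c1", h)
  expect_equal(res$assignments$gene_candidate_id, "gA")
  expect_equal(nrow(res$accepted_hits), 1L)

  # identity exactly at the bound is rejected ("higher than" is strict)
  h90 <- mk_hits("c1", "gA", qs = 1L, qe = 100L, ss = 1L, se = 100L,
                 identity = 90)
  expect_equal(nrow(assign_contig("c1", h90)$assignments), 0L)

  # 40 novel bases exactly is accepted ("at least" is inclusive)
  h40 <- mk_hits("c1", "gA", qs = 1L, qe = 40L, ss = 1L, se = 40L,
                 identity = 95)
  expect_equal(nrow(assign_contig("c1", h40)$assignments), 1L)
})

test_that("contig assignment is order-deterministic and monotone in its thresholds", {
  set.seed(41)
  h <- mk_hits("c1", sample(c("gA", "gB", "gC"), 12, TRUE),
               qs = sample(1:300, 12), qe = 0L, ss = 1L, se = 1L,
               identity = round(runif(12, 85, 100), 1),
               bitscore = sample(50:300, 12))
  h$q_end <- pmin(400L, h$q_start + sample(30:120, 12, TRUE))
  h$s_end <- h$q_end - h$q_start + 1L
  h$aln_length <- h$q_end - h$q_start + 1L
  base <- assign_contig("c1", h)
  for (i in 1:5) {
    perm <- h[sample(nrow(h)), , drop = FALSE]
    expect_equal(assign_contig("c1", perm)$accepted_hits,
                 base$accepted_hits, ignore_attr = TRUE)
  }
  n_accept <- function(mi, mn) nrow(assign_contig("c1", h, min_identity = mi,
                                                  min_novel_bp = mn)$accepted_hits)
  expect_true(all(diff(sapply(c(85, 90, 95, 99), n_accept, mn = 40)) <= 0L))
  expect_true(all(diff(sapply(c(10, 40, 80, 120), function(m)
    n_accept(85, m))) <= 0L))
})

test_that("uncovered regions respect the length floor and exclude N runs", {
  cov <- structure(list(target_id = "t",
                        covered = data.frame(start = c(0L, 900L),
                                             end = c(500L, 2000L))),
                   class = "coverage_map")
  expect_equal(uncovered_regions(2000L, cov, min_len = 400L),
               data.frame(start = 500L, end = 900L))
  cov399 <- structure(list(target_id = "t",
                           covered = data.frame(start = c(0L, 899L),
                                                end = c(500L, 2000L))),
                      class = "coverage_map")
  expect_equal(nrow(uncovered_regions(2000L, cov399, min_len = 400L)), 0L)
  full <- structure(list(target_id = "t",
                         covered = data.frame(start = 0L, end = 2000L)),
                    class = "coverage_map")
  expect_equal(nrow(uncovered_regions(2000L, full, min_len = 400L)), 0L)

  # a 450-base gap that is half N keeps no 400-bp run
  seqN <- paste0(rand_dna(500), strrep("N", 225), rand_dna(225),
                 rand_dna(1050))
  expect_equal(nrow(uncovered_regions(2000L, cov, min_len = 400L,
                                      target_seq = seqN)), 0L)
})

test_that("uncovered regions complement the coverage exactly (per-base oracle)", {
  set.seed(51)
  for (i in 1:20) {
    len <- sample(200:5000, 1L)
    n <- sample(0:6, 1L)
    s <- sort(sample(0:(len - 10L), n))
    e <- pmin(len, s + sample(10:900, max(n, 1L), TRUE)[seq_len(n)])
    keep <- s < e
    cov <- structure(list(target_id = "t",
                          covered = interval_union_for_test(s[keep], e[keep])),
                     class = "coverage_map")
    unc <- uncovered_regions(len, cov, min_len = 1L)
    base_cov <- oracle_cover_bases(cov$covered$start, cov$covered$end, len)
    base_unc <- oracle_cover_bases(unc$start, unc$end, len)
    expect_identical(base_cov | base_unc, rep(TRUE, len))  # tiles the target
    expect_false(any(base_cov & base_unc))                 # without overlap
    expect_equal(unc, oracle_uncovered(base_cov, 1L), ignore_attr = TRUE)
  }
})

test_that("genomic placement distinguishes internal exons from UTR extensions", {
  feats <- gintervals("chr1", c(1000L, 3000L, 5000L), c(1500L, 3500L, 5500L), "+")
  feats$seqid <- "chr1"
  hit_at <- function(s, e, chrom = "chr1")
    mk_hits("c1", chrom, qs = 1L, qe = e - s, ss = s + 1L, se = e)
  expect_equal(classify_genomic_placement(hit_at(3800L, 4200L), feats), "internal_exon")
  expect_equal(classify_genomic_placement(hit_at(7000L, 7400L), feats,
                                          vicinity_bp = 10000L),
               "three_prime_extension")
  expect_equal(classify_genomic_placement(hit_at(200L, 600L), feats),
               "five_prime_extension")
  expect_equal(classify_genomic_placement(hit_at(200L, 600L, "chr9"), feats),
               "unplaced")
  expect_equal(classify_genomic_placement(hit_at(7000L, 7400L), feats,
                                          vicinity_bp = 1000L), "unplaced")
  # on the minus strand, upstream means to the right
  fm <- feats; fm$strand <- "-"
  expect_equal(classify_genomic_placement(hit_at(7000L, 7400L), fm),
               "five_prime_extension")
  expect_equal(classify_genomic_placement(hit_at(200L, 600L), fm),
               "three_prime_extension")
})

test_that("fragmentation classes partition any candidate set", {
  cls <- c(chr1 = "ordered", chr2 = "ordered", contig_0412 = "unplaced",
           contig_9 = "unplaced", chrU = "artificial")
  parts <- function(...) data.frame(seqid = c(...), start = 0L, end = 10L)
  expect_equal(fragmentation_class(parts("chr1"), cls), "single_location")
  expect_equal(fragmentation_class(parts("chr1", "chr2"), cls), "multi_ordered")
  expect_equal(fragmentation_class(parts("contig_0412", "contig_9"), cls),
               "multi_unplaced")
  expect_equal(fragmentation_class(parts("chr1", "contig_0412"), cls), "mixed")
  expect_equal(fragmentation_class(parts("chr1", "chrU"), cls), "mixed")
  set.seed(61)
  classes <- replicate(50, {
    n <- sample(1:3, 1L)
    fragmentation_class(parts(sample(names(cls), n)), cls)
  })
  tab <- table(factor(classes, levels = c("single_location", "multi_ordered",
                                          "multi_unplaced", "mixed")))
  expect_equal(sum(tab), 50L)
})

test_that("gathering parts appends contig locations and reports conflicts", {
  cand <- data.frame(candidate_id = "candX", seqid = "chrX",
                     start = 100L, end = 900L, stringsAsFactors = FALSE)
  asg <- data.frame(contig_id = c("tigA", "tigA", "tigB"),
                    gene_candidate_id = c("candX", "candX", "candX"),
                    stringsAsFactors = FALSE)
  loc <- data.frame(contig_id = c("tigA", "tigB"),
                    seqid = c("contig_77", "contig_78"),
                    start = c(0L, 5L), end = c(400L, 300L),
                    stringsAsFactors = FALSE)
  res <- gather_parts(asg, cand, loc)
  expect_equal(nrow(res$parts), 3L)  # deduplicated by (seqid, interval)
  expect_equal(nrow(res$conflicts), 0L)

  asg2 <- rbind(asg, data.frame(contig_id = "tigA",
                                gene_candidate_id = "candY"))
  res2 <- gather_parts(asg2, cand, loc)
  expect_equal(res2$conflicts$contig_id, "tigA")
  expect_match(res2$conflicts$candidate_ids, "candX,candY")

  res3 <- gather_parts(asg[0, ], cand, loc)
  expect_equal(res3$parts, cand, ignore_attr = TRUE)
})
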