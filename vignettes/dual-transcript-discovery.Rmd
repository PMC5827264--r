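---
title: "Dual transcript discovery post-processing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual transcript discovery post-processing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualtx)
```

## The procedure

RNA-seq quantification against a fragmented draft genome loses read
pairs in two characteristic ways: transcribed sequence missing from the
assembly (gaps, absent microchromosomes) has no feature to be counted
against, and genes whose parts are scattered over ordered chromosomes
and unplaced contigs shed the chimeric pairs that span their parts.
`dualtx` implements the post-processing that reconciles two transcript
catalogues — a genome-guided one (gene candidates with exon features on
the assembly) and a genome-independent de novo one (isoform sequences
grouped per gene) — into a single gene model that recovers both loss
modes, then quantifies reads against it.

The stages, with their governing parameters:

| stage | rule | parameter (default) |
|---|---|---|
| read QC | drop a pair if either mate's median Phred < threshold | 28, strict |
| annotation merge | identical intron chains kept once; discordant genes resolved by total exonic length | ≥ 1 bp overlap defines discordance |
| contig assignment | accept a hit iff identity > bound and it adds ≥ novelty bp | 90 (strict), 40 bp (inclusive) |
| region extraction | keep maximal uncovered runs ≥ floor, N runs uncoverable | 400 bp |
| consensus | ungapped plus-strand shared blocks appear once; unique segments inserted, never dropped | identity ≥ 90, block ≥ 20 bp |
| artificial chromosome | concatenate retained regions with N spacers | 250 bp = 2×50 bp reads + 150 bp insert |
| naming, nucleotide tier | chicken identity > 90 or other-bird ≥ 75, both-axis coverage ≥ 50% | strict/inclusive asymmetry deliberate |
| naming, protein tier | homology ≥ 30%, query coverage ≥ 50%, accession map | inclusive |
| ORF floor | protein tiers require longest ORF ≥ 100 aa | codons incl. ATG, excl. stop |
| counting | both mates on one gene's exons, strand-matched; chimeric pairs allowed | min overlap 1 bp |

## Coordinate conventions

Internally every interval is 0-based half-open. GTF, SAM and the
12-column tabular hit format are all 1-based inclusive; conversion
happens once, in the IO module, by `(start - 1, end)` and its inverse,
so there is a single place to audit off-by-one errors. Minus-strand
subject hits (descending subject coordinates in the tabular format) are
normalised to ascending coordinates plus an explicit strand field at
parse time, because all downstream interval algebra assumes
`start < end`. Sequence case is preserved verbatim but compared
case-insensitively: the pipeline's alignment steps run without masking,
so case carries no meaning.

## The ungapped block engine

Shared-block detection (`shared_blocks()`) and the toy aligner
(`toy_align()`) share one engine: shared k-mers (k = 12, floored by the
minimum block length) nominate diagonals; each diagonal is scanned for
maximal exact runs; adjacent runs on a diagonal are fused across
mismatches under ungapped local-alignment scoring (+2 match, −3
mismatch), with the extra condition that the weaker run must be at least
4 bp — a fusion must be paid for by genuine signal, so a long run can
never absorb unrelated sequence merely because its global identity
would still clear the bar. N never matches, so assembly-gap sequence
cannot align. Blocks are then selected greedily by descending length
(ties: leftmost on the consensus); a candidate that overlaps an accepted
block is trimmed out of it rather than discarded, which matters when a
maximal run extends a base or two across an exon junction by
coincidence.

## Consensus semantics

`build_consensus()` seeds with the longest isoform (ties broken by
lexicographic id — the fold order of the remaining isoforms, descending
length, is a determinism choice; nothing in the merge depends on it for
exon-subset isoforms) and folds the others through
`shared_blocks()` + `merge_isoform()`. Isoform segments outside the
shared chain are inserted **adjacent to their flanking shared block**
(prefix before the first block, inter-block segments at the upstream
block's end, suffix after the last block) rather than at the absolute
consensus ends: absolute prepending/appending would break
transcriptional order whenever the consensus already extends beyond the
shared chain. When both sequences have unique material between the same
two shared blocks their relative order is genuinely undecidable from
pairwise ungapped comparisons; the isoform's segment is placed first,
deterministically. Non-colinear (rearranged) block chains cannot be
represented by an ungapped plus-strand merge, so the largest colinear
chain is kept and the rest dropped with a warning — a logged drop being
preferable to a silent misassembly. An isoform with no shared block at
all is appended whole: sequence unique to a single transcript is
deliberately retained, since removing it is exactly the failure mode
this consensus construction exists to avoid.

Provenance is tracked per base (contributing isoform and position), so
the derived provenance table tiles the consensus without overlap; a
separate support log records, per isoform, which of its segments were
shared and which unique, so fully-shared isoforms remain visible.

## Counting semantics

`fragment_strand()` encodes fr-firststrand chemistry: the first-in-pair
read is antisense to the transcript, so first-in-pair-reverse means a
plus-strand fragment. Fragments are then matched to features of the
*same* strand. This is one canonical convention rather than two stacked
inversions (a reverse-stranded counter matching opposite strands would
behave identically); pairs whose mates report contradictory orientations
cannot be strand-assigned and fall through to `no_feature`. A pair is
counted for the single gene whose exons both mates overlap, *including*
mates on different sequences when both belong to that gene — the
chimeric tolerance that recovers fragmented genes. Pairs matching two or
more genes are `ambiguous`; mates hitting two different single genes are
`chimeric_unresolved` (how such pairs were resolved originally is not
stated anywhere, so they are reported, never counted); duplicates
(0x400) and secondary/multi-mapping records (0x100) are excluded — the
consensus construction exists precisely so that multi-mapping does not
discard the pairs of redundant isoform sequence. Mate reference spans
come from the CIGAR when present and fall back to the fixed read length
otherwise.

## The toy-world generator

`make_toy_world()` emulates the study conditions the pipeline targets:
a genome of 2 ordered chromosomes and 4 unplaced contigs; 12 genes of
4–6 exons (200–400 bp) with introns of 100–300 bp on both strands; 25%
of genes fragmented across two sequences, cycling through the three
fragmentation classes (two ordered chromosomes, two unplaced contigs,
mixed); one gene in six carrying a single internal exon (420–550 bp)
absent from the genome — present only in transcripts, the "gap" case;
2–3 exon-subset isoforms per gene; strand-specific 50-bp paired-end
reads with the insert fixed at its 150-bp mean (the simplest model
satisfying the stated geometry; variance would only blur fragment
endpoints); and base qualities from a two-component mixture
(Phred ≈ 38 ± 2 versus 24 ± 2, 5% low), so the median-28 gate has work
on both sides. Biotype composition: one rRNA-named miscellaneous gene,
three ncRNAs (long ORFs destroyed by targeted stop-codon insertion),
one putative and one uncharacterized protein (coding but absent from
the reference database, with and without a domain record), and six
named protein-coding genes present in the reference transcript
database.

Two generator details exist solely to keep truth decidable. Isoform
skip positions are at least two exons apart, because the relative order
of two exons each missing from one of the two compared sequences is not
recoverable from pairwise ungapped alignments. Exon boundaries are
nudged by up to 5 bp so consecutive exons never share their first or
last base; otherwise a maximal exact run can slip across a junction by
a coincidental base and shift a block boundary.

What the toy world does **not** emulate: sequencing errors and quality-
dependent miscalls, expression-level variation, junction-spanning
alignment (mates that span exon junctions are emitted unmapped rather
than spliced), paralogy and repeats, and real annotation noise. Passing
tests therefore demonstrate the correctness of the rules and their
composition, not robustness to noisy alignments.

Read "mapping" is an alignment-free projection of the simulator's truth
(`project_read_pairs()`): a mate maps when its 50 bp lie inside one exon
block — to genomic coordinates for placed exons, to the artificial
chromosome for hidden exons when the model includes it, and to nowhere
otherwise. This stands in for the spliced aligner, which is out of
scope at desk scale.

## Numerical and degenerate-input choices

* Hit-processing order in `assign_contig()` is fixed (bit score
  descending, e-value ascending, subject id) — the original order is
  unstated, so determinism is imposed. Novelty is measured on the
  contig (query) axis by default, the sentence's grammatical subject;
  `axis = "subject"` implements the per-candidate alternative.
* "Best coverage" in annotation merging is the larger total exonic
  length: computable without read data and aligned with the goal of
  completeness; read-depth coverage is the other defensible reading.
  Ties keep the first annotation's gene, logged.
* Name ties break by total bit score, then alphabetically. ORF length
  counts codons including the start and excluding the stop. A frame
  with neither ATG nor stop codon carries no ORF evidence and reports
  nothing; 5'-partial ORFs require a terminating stop, 3'-partial ORFs
  an ATG.
* Zero mapped pairs produce an all-zero assignment report rather than a
  division error; empty FASTA/hit files parse to empty collections;
  empty sequences in the artificial chromosome are an error.
* `uncovered_regions()` treats N runs in the target as uncoverable so
  gap sequence can neither extend nor constitute a novel region.
* The `vicinity_bp` window for 5'/3'-extension calls defaults to
  10 kb: wide enough for typical UTR distances, narrow enough not to
  cross neighbouring toy genes; it is a parameter, not a claim.

## Problem sizes

The shipped tests and the acceptance script run toy worlds of 8–12
genes with 300–600 read pairs and sweep each threshold over a grid of
one to two dozen points around its value; a full pipeline run takes a
few seconds on one CPU. These sizes were chosen as the smallest at
which every fragmentation class, biotype and loss mode is exercised
simultaneously.

## Known limitations

The consensus merge is pairwise and ungapped: allelic indels between
isoforms of one gene produce block breaks, and truly rearranged
transcripts lose their out-of-chain blocks (with a warning). The SAM
reader is minimal by design (FLAG/RNAME/POS/MAPQ/CIGAR of text SAM);
BAM and full SAM semantics are out of scope. The naming cascade
consumes precomputed hit and evidence tables; it does not run any
search tool. Orientation-contradictory chimeric pairs (one mate on a
minus-strand genomic feature, the other on the plus-oriented artificial
chromosome) cannot be strand-assigned under the per-pair FLAG
convention and are left uncounted; the same pairs are lost by the
FLAG-based strand split the convention mirrors.
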