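Package: dualtx
Title: Dual Transcript-Discovery Post-Processing for Fragmented Draft Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for reconciling genome-guided gene
    candidates with de novo assembled transcripts on fragmented draft
    genomes. Implements a median-quality read gate, annotation merging by
    intron-chain identity, assignment of de novo contigs to gene candidates
    by novel-coverage rules, correction of gene fragmentation across
    chromosomes and unplaced contigs, construction of non-redundant
    consensus (superTranscript-like) gene sequences and an artificial
    chromosome of novel sequence, a tiered gene-naming and biotype
    classification cascade, strand-specific duplicate-aware and
    chimeric-tolerant fragment counting, and a deterministic toy-world
    simulator with a small ungapped aligner for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
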