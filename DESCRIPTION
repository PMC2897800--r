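Package: ClipIndel
Title: Small Insertion and Deletion Detection from Soft-Clipped Reads
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects small (under 10 nt) genomic insertions and deletions
    from single-end short-read alignments by analysing partially mapped
    (end soft-clipped) reads. At every reference position adjacent to a
    run of clipped bases it computes a Jaccard-style breakpoint statistic
    r -- the intersection-over-union of the read sets covering the
    position and its neighbour in the clip direction -- builds a consensus
    of the clipped tails, and classifies the event as an insertion or
    deletion with an inferred variant sequence. A companion pileup-based
    single-base variant caller, a candidate filter stack (r threshold,
    minimum clipped-read support, known-polymorphism and target-boundary
    exclusion, cross-sample recurrence), and a read simulator with planted
    variants and truth sets for recovery scoring are included, together
    with a command-line interface over the exome-capture workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicAlignments,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
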