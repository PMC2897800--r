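test_that("pileup counts aligned bases only", {
    pa <- paFromRows(list(
        list(readId = "a", start = 101L, end = 103L, seq = "CCC"),
        list(readId = "b", start = 101L, end = 103L, seq = "CCC"),
        list(readId = "c", start = 101L, end = 103L, seq = "CCC"),
        ## clipped bases over 104+ must not be counted
        list(readId = "d", start = 101L, end = 103L, seq = "CCCGGGG",
             rightClip = 4L)))
    p <- pileupCounts(pa)
    expect_equal(nrow(p), 3L)                  # only covered positions
    col <- p[p$pos == 101L, ]
    expect_equal(col$C, 4L)
    expect_equal(col$depth, 4L)
    expect_false(104L %in% p$pos)
    expect_false(any(p$G > 0L))
})

test_that("single-base calling applies strict 75% and inclusive depth 3", {
    ref <- toyReference(strrep("A", 200))
    mkPile <- function(depth, alt) data.frame(
        seqname = "t", pos = 100L, A = depth - alt, C = alt, G = 0L,
        T = 0L, N = 0L, depth = depth, stringsAsFactors = FALSE)
    ## 3 of 4 is exactly 75%: must NOT call
    expect_equal(nrow(callSnvs(mkPile(4L, 3L), ref)), 0L)
    ## 4 of 4 calls with fraction 1
    out <- callSnvs(mkPile(4L, 4L), ref)
    expect_equal(nrow(out), 1L)
    expect_equal(out$alt, "C")
    expect_equal(out$fraction, 1)
    ## depth 2 is below the minimum even at 100%
    expect_equal(nrow(callSnvs(mkPile(2L, 2L), ref)), 0L)
    ## exhaustive grid: call iff depth >= 3 and alt/depth > 0.75
    for (d in 2:10) for (a in 0:d) {
        called <- nrow(callSnvs(mkPile(d, a), ref)) == 1L
        expect_equal(called, d >= 3L && a / d > 0.75,
                     info = sprintf("depth %d alt %d", d, a))
    }
    ## a tie between alternates yields no call
    tie <- data.frame(seqname = "t", pos = 100L, A = 0L, C = 3L, G = 3L,
                      T = 0L, N = 0L, depth = 6L, stringsAsFactors = FALSE)
    expect_equal(nrow(callSnvs(tie, ref)), 0L)
    ## N counts in the depth denominator
    withN <- data.frame(seqname = "t", pos = 100L, A = 0L, C = 3L, G = 0L,
                        T = 0L, N = 1L, depth = 4L, stringsAsFactors = FALSE)
    expect_equal(nrow(callSnvs(withN, ref)), 0L)   # 3/4 not > 0.75
})

test_that("consequence classification is strand- and frame-aware", {
    ## + strand gene: codons CGA TTT -> Arg Phe
    ref <- toyReference(paste0(strrep("A", 100), "CGATTT", strrep("A", 94)))
    cds <- data.frame(seqname = "t", start = 101L, end = 106L,
                      strand = "+", frame = 0L, gene = "g1",
                      stringsAsFactors = FALSE)
    snv <- function(pos, alt) data.frame(
        sample = "s", seqname = "t", pos = pos, ref = "x", alt = alt,
        depth = 10L, altCount = 10L, fraction = 1,
        stringsAsFactors = FALSE)
    ## CGA -> CGG: both Arg, synonymous
    out <- annotateConsequence(snv(103L, "G"), cds, ref)
    expect_equal(out$consequence, "synonymous")
    ## CGA -> CCA: Arg -> Pro
    out <- annotateConsequence(snv(102L, "C"), cds, ref)
    expect_equal(out$consequence, "nonsynonymous")
    ## outside any CDS
    out <- annotateConsequence(snv(50L, "C"), cds, ref)
    expect_equal(out$consequence, "noncoding")
    ## codon truncated by the interval end
    cdsTrunc <- transform(cds, end = 105L)
    out <- annotateConsequence(snv(105L, "C"), cdsTrunc, ref)
    expect_equal(out$consequence, "unknown")
    ## no annotation at all
    out <- annotateConsequence(snv(103L, "G"), NULL, ref)
    expect_equal(out$consequence, "unknown")
})

test_that("consequence calls agree with a whole-CDS translation oracle", {
    ## 300 nt toy gene; scan every CDS position x all 3 alternates on both
    ## strands and compare against translating the full mutated CDS.
    set.seed(321)
    geneLen <- 300L
    refStr <- paste0(randomSeq(50), randomSeq(geneLen), randomSeq(50))
    ref <- toyReference(refStr)
    for (strand in c("+", "-")) {
        cds <- data.frame(seqname = "t", start = 51L,
                          end = 50L + geneLen, strand = strand,
                          frame = 0L, gene = "g", stringsAsFactors = FALSE)
        oracle <- function(pos, alt) {
            s <- refStr
            substr(s, pos, pos) <- alt
            extract <- function(x) {
                cdsSeq <- Biostrings::DNAString(substr(x, 51L,
                                                       50L + geneLen))
                if (strand == "-")
                    cdsSeq <- Biostrings::reverseComplement(cdsSeq)
                as.character(Biostrings::translate(cdsSeq,
                                                   no.init.codon = TRUE))
            }
            if (extract(s) == extract(refStr)) "synonymous" else
                "nonsynonymous"
        }
        positions <- seq(51L, 50L + geneLen)
        ## subsample positions for speed; exhaustive over alternates
        for (pos in positions[seq(1, geneLen, by = 7)]) {
            refBase <- substr(refStr, pos, pos)
            for (alt in setdiff(c("A", "C", "G", "T"), refBase)) {
                got <- annotateConsequence(
                    data.frame(sample = "s", seqname = "t", pos = pos,
                               ref = refBase, alt = alt, depth = 10L,
                               altCount = 10L, fraction = 1,
                               stringsAsFactors = FALSE), cds, ref)
                expect_equal(got$consequence, oracle(pos, alt),
                             info = sprintf("%s pos %d %s>%s", strand,
                                            pos, refBase, alt))
            }
        }
    }
})

test_that("the multi-sample pipeline removes systematic and known positions", {
    ## hand-built alignments: 3 samples, 60x target-less mini-genome
    set.seed(5)
    refStr <- randomSeq(300)
    ref <- toyReference(refStr)
    mkSample <- function(alt100 = NULL, alt110 = NULL) {
        rows <- lapply(1:12, function(i) {
            start <- 10L * i
            s <- substr(refStr, start, start + 49L)
            list(readId = sprintf("r%02d", i), start = start,
                 end = start + 49L, seq = s)
        })
        pa <- alnTable(paFromRows(rows))
        patch <- function(pa, pos, alt) {
            hit <- pa$start <= pos & pa$end >= pos
            pa$seq[hit] <- vapply(which(hit), function(k) {
                s <- pa$seq[k]
                substr(s, pos - pa$start[k] + 1L,
                       pos - pa$start[k] + 1L) <- alt
                s
            }, character(1))
            pa
        }
        if (!is.null(alt100)) pa <- patch(pa, 100L, alt100)
        if (!is.null(alt110)) pa <- patch(pa, 110L, alt110)
        PartialAlignments(pa)
    }
    altOf <- function(pos) setdiff(c("A", "C", "G", "T"),
                                   substr(refStr, pos, pos))[1]
    alns <- list(s1 = mkSample(alt100 = altOf(100L)),
                 s2 = mkSample(alt100 = altOf(100L)),
                 s3 = mkSample(alt100 = altOf(100L),
                               alt110 = altOf(110L)))
    out <- snvPipeline(alns, ref, maxSamples = 2L)
    all <- do.call(rbind, out)
    expect_false(100L %in% all$pos)            # 3 samples: systematic
    expect_true(110L %in% all$pos)             # singleton survives
    ## known-position exclusion
    known <- GenomicRanges::GRanges("t", IRanges::IRanges(110, 110))
    out <- snvPipeline(alns, ref, known = known, maxSamples = 2L)
    expect_equal(sum(vapply(out, nrow, integer(1))), 0L)
    ## nonsynonymousOnly without annotation is an error
    expect_error(snvPipeline(alns, ref, nonsynonymousOnly = TRUE),
                 "CDS")
})
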