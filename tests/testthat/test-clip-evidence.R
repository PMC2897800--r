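test_that("clip events sit at the correct breakpoints with outward tails", {
    seq50 <- paste0(strrep("A", 40), "TTAGCCCGGT")
    pa <- paFromRows(list(
        list(readId = "right", start = 101L, end = 140L, seq = seq50,
             rightClip = 10L),
        list(readId = "left", start = 101L, end = 140L,
             seq = paste0("TTAGCCCGGT", strrep("A", 40)), leftClip = 10L),
        list(readId = "full", start = 201L, end = 250L,
             seq = strrep("A", 50))))
    ev <- collectClipEvents(pa)
    expect_equal(nrow(ev), 2L)
    r <- ev[ev$readId == "right", ]
    expect_equal(r$p, 140L)                     # last aligned base
    expect_equal(r$direction, "right")
    expect_equal(r$clipSeq, "TTAGCCCGGT")       # read order = outward
    l <- ev[ev$readId == "left", ]
    expect_equal(l$p, 101L)                     # first aligned base
    expect_equal(l$direction, "left")
    expect_equal(l$clipSeq, "TGGCCCGATT")       # reversed = outward from p

    ## a read clipped at both ends yields two events
    both <- paFromRows(list(list(
        readId = "b", start = 110L, end = 139L,
        seq = paste0("CCCCC", strrep("A", 30), "GGGGGGGGGG"),
        leftClip = 5L, rightClip = 10L)))
    expect_equal(nrow(collectClipEvents(both)), 2L)

    ## internal-indel reads are excluded unless asked
    withD <- paFromRows(list(list(
        readId = "d", start = 101L, end = 140L,
        seq = paste0(strrep("A", 40), "TTTTTTTTTT"), rightClip = 10L,
        hasIndelOps = TRUE)))
    expect_equal(nrow(collectClipEvents(withD)), 0L)
    expect_equal(nrow(collectClipEvents(withD, countMapperIndels = TRUE)),
                 1L)
})

test_that("site counts reproduce the worked intersection/union example", {
    ## 6 reads span both p=100 and 101; 4 more end exactly at p
    pa <- paFromSpans(starts = rep(51L, 10),
                      ends = c(rep(150L, 6), rep(100L, 4)))
    sc <- siteCounts(pa, data.frame(seqname = "t", p = 100L,
                                    direction = "right"))
    expect_equal(sc$Np, 10L)
    expect_equal(sc$Npm1, 6L)
    expect_equal(sc$Nboth, 6L)
    expect_equal(sc$r, 6 / (10 + 6 - 6))

    ## all reads covering p end at p: empty intersection, r = 0
    pa <- paFromSpans(rep(61L, 40), rep(100L, 40))
    sc <- siteCounts(pa, data.frame(seqname = "t", p = 100L,
                                    direction = "right"))
    expect_equal(sc$r, 0)

    ## identical read sets: r = 1
    pa <- paFromSpans(rep(51L, 7), rep(150L, 7))
    sc <- siteCounts(pa, data.frame(seqname = "t", p = 100L,
                                    direction = "right"))
    expect_equal(sc$r, 1)

    ## no coverage at all: r defined as 1 (least indel-like)
    sc <- siteCounts(pa, data.frame(seqname = "t", p = 500L,
                                    direction = "right"))
    expect_equal(sc$r, 1)

    ## out-of-bounds neighbour is signalled, not silently dropped
    sc <- siteCounts(pa, data.frame(seqname = "t", p = 1L,
                                    direction = "left"),
                     seqlengths = c(t = 1000L))
    expect_false(sc$evaluable)
    expect_true(is.na(sc$r))
})

test_that("r matches a brute-force set oracle on randomized pileups", {
    set.seed(4242)
    for (i in 1:250) {
        n <- sample(1:60, 1)
        starts <- sample(1:150, n, replace = TRUE)
        ends <- starts + sample(20:50, n, replace = TRUE)
        p <- sample(5:195, 1)
        dir <- sample(c("right", "left"), 1)
        sc <- siteCounts(paFromSpans(starts, ends),
                         data.frame(seqname = "t", p = p, direction = dir))
        expect_identical(sc$r, jaccardOracle(starts, ends, p, dir))
    }
})

test_that("r is monotone in the expected directions", {
    set.seed(99)
    for (i in 1:50) {
        n <- sample(2:30, 1)
        starts <- sample(80:100, n, replace = TRUE)
        ends <- starts + sample(10:40, n, replace = TRUE)
        p <- 100L
        base <- siteCounts(paFromSpans(starts, ends),
                           data.frame(seqname = "t", p = p,
                                      direction = "right"))$r
        ## adding a read covering both p and p+1 never decreases r
        rBoth <- siteCounts(paFromSpans(c(starts, 90L), c(ends, 120L)),
                            data.frame(seqname = "t", p = p,
                                       direction = "right"))$r
        expect_gte(rBoth, base)
        ## adding a read covering only p never increases r
        rOnly <- siteCounts(paFromSpans(c(starts, 90L), c(ends, 100L)),
                            data.frame(seqname = "t", p = p,
                                       direction = "right"))$r
        expect_lte(rOnly, base)
    }
})

test_that("tail consensus follows plurality with deterministic ties", {
    ## unanimity
    g <- gapConsensus(rep("TTAGC", 5))
    expect_equal(g$consensus, "TTAGC")
    expect_equal(g$support, 5L)
    expect_true(all(g$agreement == 1))

    ## per-position plurality: G wins 2/3 at offset 4
    g <- gapConsensus(c("TTAGC", "TTAGC", "TTACC"), agreement = 0.5)
    expect_equal(g$consensus, "TTAGC")
    expect_equal(g$agreement[4], 2 / 3)

    ## truncation when fewer than minSupport tails still extend
    g <- gapConsensus(c("TTAGC", "TTAGC", "TT"), minSupport = 3L)
    expect_equal(g$consensus, "TT")

    ## lexicographic tie-break: A before C
    g <- gapConsensus(c("A", "C"), agreement = 0.5)
    expect_equal(g$consensus, "A")
})

test_that("classification reproduces the worked deletion and insertion", {
    ## reference continuation beyond p is ACGTACGTA; consensus TACGTA
    ## matches perfectly from offset 4 => deletion of 3 (ACG)
    ref <- toyReference(paste0(strrep("G", 100), "ACGTACGTA",
                               strrep("T", 20)))
    call <- classifyIndel("TACGTA", ref, "t", 100L, "right")
    expect_equal(call$type, "deletion")
    expect_equal(call$length, 3L)
    expect_equal(call$varSeq, "ACG")
    expect_equal(call$variantStart, 101L)

    ## consensus TTAAC: after skipping TTA, AC matches the continuation
    ref <- toyReference(paste0(strrep("G", 100), "ACTTGTTGC"))
    call <- classifyIndel("TTAAC", ref, "t", 100L, "right")
    expect_equal(call$type, "insertion")
    expect_equal(call$length, 3L)
    expect_equal(call$varSeq, "TTA")
    expect_equal(call$variantStart, 100L)

    ## consensus equal to the reference continuation: no variant
    call <- classifyIndel("ACTTG", ref, "t", 100L, "right")
    expect_equal(call$type, "unresolved")

    ## too-short consensus is not classified
    call <- classifyIndel("ACT", ref, "t", 100L, "right")
    expect_equal(call$type, "unresolved")
})

test_that("classification inverts planted variants for all lengths and both directions", {
    set.seed(777)
    refStr <- randomSeq(400)
    ref <- toyReference(refStr)
    for (L in 1:9) {
        ## deletion, right clip at p = 150: tail reads ref after the gap
        p <- 150L
        tail <- substr(refStr, p + 1L + L, p + 12L + L)
        call <- classifyIndel(tail, ref, "t", p, "right")
        expect_equal(call$type, "deletion", info = paste("DEL right", L))
        expect_equal(call$length, L)
        expect_equal(call$varSeq, substr(refStr, p + 1L, p + L))

        ## deletion, left clip at p' = first base after the deleted span
        pl <- p + L + 1L
        tailL <- .revStrTest(substr(refStr, p - 11L, p))
        call <- classifyIndel(tailL, ref, "t", pl, "left")
        expect_equal(call$type, "deletion", info = paste("DEL left", L))
        expect_equal(call$length, L)
        expect_equal(call$variantStart, p + 1L)

        ## insertion after p: right tail = inserted bases + continuation
        ins <- refStr                      # build S differing at base 1
        S <- paste(rep("A", L), collapse = "")
        if (substr(refStr, p + 1L, p + 1L) == "A")
            S <- paste(rep("C", L), collapse = "")
        tail <- paste0(S, substr(refStr, p + 1L, p + 12L - L))
        call <- classifyIndel(tail, ref, "t", p, "right")
        expect_equal(call$type, "insertion", info = paste("INS right", L))
        expect_equal(call$length, L)
        expect_equal(call$varSeq, S)

        ## insertion, left clip at p+1: tail = rev(S) + rev(upstream)
        if (substr(refStr, p, p) == substr(S, 1, 1))
            S <- paste(rep("G", L), collapse = "")
        tailL <- paste0(.revStrTest(S),
                        .revStrTest(substr(refStr, p - 11L + L, p)))
        call <- classifyIndel(tailL, ref, "t", p + 1L, "left")
        expect_equal(call$type, "insertion", info = paste("INS left", L))
        expect_equal(call$length, L)
        expect_equal(call$varSeq, S)
        expect_equal(call$variantStart, p)
    }
})

test_that("candidate calling skips exact target boundary positions", {
    ## clip events at a target start position produce no candidate there
    refStr <- paste0(strrep("A", 100), randomSeq(200))
    ref <- toyReference(refStr)
    tg <- GenomicRanges::GRanges("t", IRanges::IRanges(101, 200))
    tail <- substr(refStr, 105, 112)
    pa <- paFromRows(lapply(1:6, function(i) list(
        readId = paste0("r", i), start = 51L, end = 101L,
        seq = paste0(strrep("A", 51), tail), rightClip = 8L)))
    candAt <- callCandidates(pa, ref, targets = NULL)
    expect_true(101L %in% candidateTable(candAt)$p)
    candNo <- callCandidates(pa, ref, targets = tg)
    expect_false(101L %in% candidateTable(candNo)$p)
})
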