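## Shared fixture builders.  Everything is generated in code at test time;
## datasets used by several files are memoised for the session.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, maker) {
    if (!exists(name, envir = .fixtureCache))
        assign(name, maker(), envir = .fixtureCache)
    get(name, envir = .fixtureCache)
}

## Minimal PartialAlignments from aligned spans (no clips, all-A reads).
paFromSpans <- function(starts, ends, seqname = "t") {
    n <- length(starts)
    PartialAlignments(data.frame(
        readId = sprintf("r%03d", seq_len(n)), seqname = seqname,
        start = starts, end = ends, strand = "+",
        seq = strrep("A", ends - starts + 1L),
        leftClip = 0L, rightClip = 0L, mismatches = 0L, mapq = 60L,
        isUnique = TRUE, hasIndelOps = FALSE, stringsAsFactors = FALSE))
}

## PartialAlignments from explicit rows with clips.
paFromRows <- function(rows) {
    PartialAlignments(do.call(rbind, lapply(rows, function(r) {
        data.frame(readId = r$readId, seqname = r$seqname %||% "t",
                   start = r$start, end = r$end,
                   strand = r$strand %||% "+", seq = r$seq,
                   leftClip = r$leftClip %||% 0L,
                   rightClip = r$rightClip %||% 0L,
                   mismatches = r$mismatches %||% 0L,
                   mapq = r$mapq %||% 60L,
                   isUnique = r$isUnique %||% TRUE,
                   hasIndelOps = r$hasIndelOps %||% FALSE,
                   stringsAsFactors = FALSE)
    })))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Independent brute-force oracle for the breakpoint statistic: materialise
## the two read sets and take |intersection| / |union|.
jaccardOracle <- function(starts, ends, p, direction) {
    q <- if (direction == "right") p + 1L else p - 1L
    A <- which(starts <= p & ends >= p)
    B <- which(starts <= q & ends >= q)
    u <- union(A, B)
    if (length(u) == 0L) return(1)
    length(intersect(A, B)) / length(u)
}

## Write a small SAM file from header info + alignment lines.
writeToySam <- function(lines, seqname = "t", seqlen = 1000L,
                        file = tempfile(fileext = ".sam")) {
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 sprintf("@SQ\tSN:%s\tLN:%d", seqname, seqlen),
                 lines), file)
    file
}

## A toy reference with a known sequence.
toyReference <- function(seq, name = "t") {
    x <- Biostrings::DNAStringSet(seq)
    names(x) <- name
    x
}

.revStrTest <- function(s) {
    vapply(strsplit(s, "", fixed = TRUE),
           function(ch) paste(rev(ch), collapse = ""), character(1))
}

## Random reference string of length n (uses current RNG state).
randomSeq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## The error-free single-sample study design: 100 kb reference, 20 targets,
## depth 40, read length 50, no errors, the four validated variant sizes
## (deletions of 3 and 6 nt, insertions of 5 and 3 nt).
errorFreeDataset <- function() {
    cachedFixture("errorFree", function() {
        cfg <- simConfig(refLength = 100000L, nTargets = 20L,
                         meanDepth = 40, errorRate = 0, nSamples = 1L)
        vars <- data.frame(type = c("DEL", "DEL", "INS", "INS"),
                           length = c(3L, 6L, 5L, 3L), samples = "1",
                           stringsAsFactors = FALSE)
        ds <- simulateDataset(vars, cfg, seed = 20100527L)
        dir <- file.path(tempdir(), "clipindel-errorfree")
        writeDataset(ds, dir)
        list(ds = ds, dir = dir)
    })
}

## Run the indel workflow on the error-free dataset (memoised).
errorFreeRun <- function() {
    cachedFixture("errorFreeRun", function() {
        fx <- errorFreeDataset()
        runParMap(stats::setNames(file.path(fx$dir, "sample01.sam"),
                                  "sample01"),
                  reference = file.path(fx$dir, "reference.fasta"),
                  targets = file.path(fx$dir, "targets.bed"))
    })
}
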