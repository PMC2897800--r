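## Candidate filter stack.  Filters annotate rather than delete: each
## candidate carries the set of filter names it fails, and a PASS candidate
## fails none.  Every filter is evaluated independently of the others.

#' Reference interval implicated by a candidate
#'
#' For a deletion this is the deleted span; for insertions and unresolved
#' calls it is the breakpoint position and its neighbour in the clip
#' direction (the two bases flanking the putative event).
#'
#' @param cand one row of a candidate table (data.frame)
#' @return integer vector `c(start, end)`, 1-based inclusive.
#' @export
affectedInterval <- function(cand) {
    if (cand$callType == "deletion") {
        c(cand$variantStart, cand$variantStart + cand$callLength - 1L)
    } else if (cand$direction == "right") {
        c(cand$p, cand$p + 1L)
    } else {
        c(cand$p - 1L, cand$p)
    }
}

#' Individual candidate filters
#'
#' `filterR` passes iff r < rThreshold (strict); `filterSupport` passes iff
#' support >= minReads (inclusive); `filterKnownVariants` fails when the
#' affected interval intersects a known polymorphic position;
#' `filterBoundary` fails when the breakpoint p lies at, or within
#' `boundaryWindow` bases of, a target start or end.
#'
#' @param cand a candidate table (data.frame with the
#'   [IndelCandidates-class] columns); vectorized over rows
#' @param config a [FilterConfig-class]
#' @return logical vector, TRUE = pass.
#' @export
filterR <- function(cand, config = filterConfig()) {
    cand$r < config@rThreshold
}

#' @rdname filterR
#' @export
filterSupport <- function(cand, config = filterConfig()) {
    cand$support >= config@minReads
}

#' @rdname filterR
#' @param known width-1 GRanges of known polymorphic positions (from
#'   [readKnownVariants()]); NULL means no exclusion
#' @export
filterKnownVariants <- function(cand, known = NULL) {
    n <- nrow(cand)
    if (is.null(known) || length(known) == 0L || n == 0L)
        return(rep(TRUE, n))
    pass <- logical(n)
    for (i in seq_len(n)) {
        iv <- affectedInterval(cand[i, , drop = FALSE])
        hit <- GenomicRanges::countOverlaps(
            GenomicRanges::GRanges(cand$seqname[i],
                                   IRanges::IRanges(iv[1], iv[2])),
            known) > 0L
        pass[i] <- !hit
    }
    pass
}

#' @rdname filterR
#' @param targets GRanges of capture targets; NULL disables the boundary
#'   filter
#' @export
filterBoundary <- function(cand, targets = NULL, config = filterConfig()) {
    n <- nrow(cand)
    if (is.null(targets) || length(targets) == 0L || n == 0L)
        return(rep(TRUE, n))
    w <- config@boundaryWindow
    sn <- as.character(GenomicRanges::seqnames(targets))
    bs <- GenomicRanges::start(targets)
    be <- GenomicRanges::end(targets)
    vapply(seq_len(n), function(i) {
        same <- sn == cand$seqname[i]
        !any(abs(cand$p[i] - bs[same]) <= w |
                 abs(cand$p[i] - be[same]) <= w)
    }, logical(1))
}

#' Annotate candidates with every failed filter
#'
#' Evaluates the r, support, known-polymorphism, boundary, and resolution
#' filters independently and records the full set of failures on each
#' candidate (comma-separated, sorted; "" = PASS so far).  The cross-sample
#' recurrence filter needs all samples at once and is applied separately by
#' [crossSampleFilter()].
#'
#' @param x an [IndelCandidates-class] object
#' @param config a [FilterConfig-class]
#' @param known optional width-1 GRanges of known polymorphic positions
#' @param targets optional GRanges of capture targets
#' @return the annotated `IndelCandidates`.
#' @export
applyFilters <- function(x, config = filterConfig(), known = NULL,
                         targets = NULL) {
    d <- candidateTable(x)
    if (nrow(d) == 0L) return(x)
    fails <- list(
        r = !filterR(d, config),
        support = !filterSupport(d, config),
        known = if (config@excludeKnown)
            !filterKnownVariants(d, known) else rep(FALSE, nrow(d)),
        boundary = !filterBoundary(d, targets, config),
        resolved = d$callType == "unresolved")
    d$filtersFailed <- vapply(seq_len(nrow(d)), function(i) {
        f <- names(fails)[vapply(fails, `[`, logical(1), i)]
        paste(sort(f), collapse = ",")
    }, character(1))
    IndelCandidates(d)
}

#' Cross-sample recurrence filter
#'
#' Variant-like signals recurring at one position across many independent
#' samples are systematic artifacts of capture, sequencing or mapping, not
#' biology.  A candidate is kept iff the number of distinct samples carrying
#' any candidate at its position is at most `maxSamples`.  The key is the
#' position only, not the allele.
#'
#' @param tables named list (one element per sample) of candidate
#'   data.frames; each must have a `seqname` column and the position column
#'   named by `posColumn`
#' @param maxSamples maximum number of samples allowed to share a position
#' @param posColumn position column used as the recurrence key
#'   (`"variantStart"` for merged indel candidates, `"pos"` for single-base
#'   candidates)
#' @param annotate if TRUE, recurrent rows are kept and `"recurrent"` is
#'   added to their `filtersFailed`; if FALSE, recurrent rows are dropped
#' @return the list of tables, recurrence-filtered/annotated.
#' @export
crossSampleFilter <- function(tables, maxSamples, posColumn = "pos",
                              annotate = FALSE) {
    stopifnot(length(tables) >= 1L)
    keyOf <- function(d) {
        pos <- d[[posColumn]]
        if (posColumn == "variantStart")     # unresolved rows have no
            pos <- ifelse(is.na(pos), d$p, pos)   # variant start; use p
        paste(d$seqname, pos)
    }
    perSample <- lapply(tables, function(d) unique(keyOf(d)))
    counts <- table(unlist(perSample))
    lapply(tables, function(d) {
        if (nrow(d) == 0L) return(d)
        recurrent <- counts[keyOf(d)] > maxSamples
        if (annotate) {
            ff <- d$filtersFailed
            ff[recurrent] <- vapply(ff[recurrent], function(s) {
                paste(sort(unique(c(strsplit(s, ",")[[1]], "recurrent"))),
                      collapse = ",")
            }, character(1))
            d$filtersFailed <- ff
            d
        } else {
            d[!recurrent, , drop = FALSE]
        }
    })
}
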