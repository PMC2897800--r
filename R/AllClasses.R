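#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.PA_COLS <- c("readId", "seqname", "start", "end", "strand", "seq",
              "leftClip", "rightClip", "mismatches", "mapq",
              "isUnique", "hasIndelOps")

#' Partially mapped single-end alignments
#'
#' Container for normalized single-end alignments with optional soft-clipped
#' ("partially mapped") ends.  One row per primary alignment.  `start`/`end`
#' are the 1-based inclusive reference coordinates of the aligned
#' (non-clipped) span; `seq` is the full read sequence as stored in the
#' alignment record (reference orientation); `leftClip`/`rightClip` give the
#' number of soft-clipped bases at each end.
#'
#' For alignments without internal indel operators the invariant
#' `leftClip + (end - start + 1) + rightClip == nchar(seq)` holds and is
#' enforced by the validity method.  Alignments whose CIGAR contains internal
#' I/D operators are flagged (`hasIndelOps`); their aligned span is still the
#' reference span, but their bases cannot be placed per-position by this
#' model, so they are excluded from clip evidence and pileups downstream.
#'
#' @slot data A [S4Vectors::DataFrame] with the columns listed above.
#' @export
setClass("PartialAlignments", representation(data = "DataFrame"))

setValidity("PartialAlignments", function(object) {
    d <- object@data
    missing <- setdiff(.PA_COLS, colnames(d))
    if (length(missing))
        return(paste("missing columns:", paste(missing, collapse = ", ")))
    if (nrow(d) == 0L) return(TRUE)
    if (any(d$leftClip < 0L) || any(d$rightClip < 0L))
        return("negative clip length")
    if (any(d$end < d$start))
        return("end < start in aligned span")
    plain <- !d$hasIndelOps
    span <- d$end - d$start + 1L
    bad <- plain & (d$leftClip + span + d$rightClip != nchar(d$seq))
    if (any(bad))
        return(sprintf("%d record(s) violate clip+span+clip == read length",
                       sum(bad)))
    TRUE
})

#' Construct a PartialAlignments object
#'
#' @param data a data.frame or DataFrame with one row per alignment and
#'   columns `readId`, `seqname`, `start`, `end`, `strand`, `seq`,
#'   `leftClip`, `rightClip`, `mismatches`, `mapq`, `isUnique`,
#'   `hasIndelOps`.
#' @return A [PartialAlignments-class] object.
#' @export
PartialAlignments <- function(data) {
    d <- as(as.data.frame(data), "DataFrame")
    for (col in c("start", "end", "leftClip", "rightClip",
                  "mismatches", "mapq"))
        if (col %in% colnames(d)) d[[col]] <- as.integer(d[[col]])
    new("PartialAlignments", data = d[, .PA_COLS, drop = FALSE])
}

#' @describeIn PartialAlignments number of alignment records
#' @param x a `PartialAlignments` object
#' @export
setMethod("length", "PartialAlignments", function(x) nrow(x@data))

setMethod("show", "PartialAlignments", function(object) {
    d <- object@data
    cat("PartialAlignments with", nrow(d), "records\n")
    if (nrow(d)) {
        nclip <- sum(d$leftClip > 0L | d$rightClip > 0L)
        cat(sprintf("  sequences: %s\n",
                    paste(unique(d$seqname), collapse = ", ")))
        cat(sprintf("  clipped at >=1 end: %d (%.1f%%)\n",
                    nclip, 100 * nclip / nrow(d)))
    }
})

#' @export
setMethod("[", "PartialAlignments", function(x, i, j, ..., drop = TRUE) {
    initialize(x, data = x@data[i, , drop = FALSE])
})

#' Extract the alignment table
#'
#' @param x a `PartialAlignments` object
#' @return a `data.frame`, one row per alignment.
#' @export
alnTable <- function(x) {
    stopifnot(is(x, "PartialAlignments"))
    as.data.frame(x@data)
}

#' Aligned (non-clipped) spans as a GRanges
#'
#' Clipped bases do not contribute: a read does not "cover" positions under
#' its clip, which is what makes the breakpoint statistic sensitive.
#'
#' @param x a `PartialAlignments` object
#' @param seqlengths optional named integer vector of reference lengths
#' @return a [GenomicRanges::GRanges] of the aligned spans, with `readId`
#'   metadata column.
#' @export
alignedRanges <- function(x, seqlengths = NULL) {
    d <- x@data
    gr <- GenomicRanges::GRanges(
        seqnames = d$seqname,
        ranges = IRanges::IRanges(start = d$start, end = d$end),
        strand = d$strand)
    S4Vectors::mcols(gr)$readId <- d$readId
    if (!is.null(seqlengths))
        GenomeInfoDb::seqlengths(gr) <-
            seqlengths[GenomeInfoDb::seqlevels(gr)]
    gr
}

## ---------------------------------------------------------------------------

.FILTER_NAMES <- c("r", "support", "known", "boundary", "resolved",
                   "recurrent")

#' Filter configuration for candidate indels
#'
#' Thresholds applied to indel candidates (and, where shared, to single-base
#' candidates).  `rThreshold` is strict (a candidate passes iff r <
#' rThreshold); `minReads` is inclusive (support >= minReads passes).
#' `boundaryWindow` widens the target start/end exclusion zone by that many
#' bases on each side (0 keeps only the exact boundary positions excluded).
#' `maxSamplesIndel`/`maxSamplesSnv` bound the number of distinct samples
#' allowed to carry a candidate at one position before it is flagged as a
#' recurrent systematic artifact.
#'
#' @export
setClass("FilterConfig", representation(
    rThreshold = "numeric",
    minReads = "integer",
    boundaryWindow = "integer",
    maxSamplesIndel = "integer",
    maxSamplesSnv = "integer",
    excludeKnown = "logical"))

setValidity("FilterConfig", function(object) {
    if (length(object@rThreshold) != 1L ||
        object@rThreshold <= 0 || object@rThreshold > 1)
        return("rThreshold must be a single value in (0, 1]")
    if (object@minReads < 1L) return("minReads must be >= 1")
    if (object@boundaryWindow < 0L) return("boundaryWindow must be >= 0")
    if (object@maxSamplesIndel < 1L || object@maxSamplesSnv < 1L)
        return("maxSamples* must be >= 1")
    TRUE
})

#' Construct a FilterConfig
#'
#' @param rThreshold strict upper bound on the breakpoint statistic r
#'   (default 0.35).
#' @param minReads minimum number of clipped reads supporting a breakpoint
#'   (default 5).
#' @param boundaryWindow extra bases around target starts/ends to exclude
#'   (default 0).
#' @param maxSamplesIndel maximum samples sharing an indel position before it
#'   is treated as systematic (default 1).
#' @param maxSamplesSnv same for single-base candidates (default 2, i.e.
#'   "fewer than 3 samples").
#' @param excludeKnown drop candidates whose affected interval covers a known
#'   polymorphic position (default TRUE).
#' @return a `FilterConfig` object.
#' @export
filterConfig <- function(rThreshold = 0.35, minReads = 5L,
                         boundaryWindow = 0L, maxSamplesIndel = 1L,
                         maxSamplesSnv = 2L, excludeKnown = TRUE) {
    new("FilterConfig",
        rThreshold = rThreshold,
        minReads = as.integer(minReads),
        boundaryWindow = as.integer(boundaryWindow),
        maxSamplesIndel = as.integer(maxSamplesIndel),
        maxSamplesSnv = as.integer(maxSamplesSnv),
        excludeKnown = excludeKnown)
}

setMethod("show", "FilterConfig", function(object) {
    cat("FilterConfig\n")
    cat("  r <", object@rThreshold, "(strict)\n")
    cat("  support >=", object@minReads, "\n")
    cat("  boundary window:", object@boundaryWindow, "bases\n")
    cat("  max samples (indel/snv):", object@maxSamplesIndel, "/",
        object@maxSamplesSnv, "\n")
    cat("  exclude known polymorphisms:", object@excludeKnown, "\n")
})

## ---------------------------------------------------------------------------

.CAND_COLS <- c("sample", "seqname", "p", "direction", "Np", "Npm1", "Nboth",
                "r", "support", "consensus", "minAgreement", "callType",
                "callLength", "callSeq", "variantStart", "identity",
                "mergedDirections", "filtersFailed")

#' Candidate indel calls at clipped-read breakpoints
#'
#' One row per (merged) candidate.  `p` is the 1-based breakpoint position
#' (last aligned base before a right clip; first aligned base after a left
#' clip).  `Np`, `Npm1`, `Nboth` are the read-set sizes behind the breakpoint
#' statistic `r`.  `support` counts the clipped reads backing the candidate
#' (summed over merged directions).  `callType` is one of `"deletion"`,
#' `"insertion"`, `"unresolved"`; for resolved calls `variantStart` is the
#' genomic start of the deleted span, or the base after which the insertion
#' occurs.  `filtersFailed` is a comma-separated list of failed filter names
#' ("" = PASS).
#'
#' @slot data a [S4Vectors::DataFrame] of candidates.
#' @export
setClass("IndelCandidates", representation(data = "DataFrame"))

setValidity("IndelCandidates", function(object) {
    d <- object@data
    missing <- setdiff(.CAND_COLS, colnames(d))
    if (length(missing))
        return(paste("missing columns:", paste(missing, collapse = ", ")))
    if (nrow(d) == 0L) return(TRUE)
    if (!all(d$callType %in% c("deletion", "insertion", "unresolved")))
        return("invalid callType")
    if (any(d$r < 0 | d$r > 1)) return("r outside [0, 1]")
    if (any(d$Nboth > pmin(d$Np, d$Npm1)))
        return("Nboth exceeds min(Np, Npm1)")
    res <- d$callType != "unresolved"
    if (any(res & (d$callLength < 1L | d$callLength > 9L)))
        return("resolved call length outside 1..9")
    if (any(res & nchar(d$callSeq) != d$callLength))
        return("variant sequence length disagrees with call length")
    TRUE
})

#' Construct an IndelCandidates object
#'
#' @param data data.frame of candidate rows (see
#'   [IndelCandidates-class]); a zero-row frame is allowed.
#' @return an `IndelCandidates` object.
#' @export
IndelCandidates <- function(data = NULL) {
    if (is.null(data) || nrow(data) == 0L) {
        d <- DataFrame(
            sample = character(), seqname = character(), p = integer(),
            direction = character(), Np = integer(), Npm1 = integer(),
            Nboth = integer(), r = numeric(), support = integer(),
            consensus = character(), minAgreement = numeric(),
            callType = character(), callLength = integer(),
            callSeq = character(), variantStart = integer(),
            identity = numeric(), mergedDirections = character(),
            filtersFailed = character())
    } else {
        d <- as(as.data.frame(data), "DataFrame")
        for (col in c("p", "Np", "Npm1", "Nboth", "support",
                      "callLength", "variantStart"))
            d[[col]] <- as.integer(d[[col]])
    }
    new("IndelCandidates", data = d[, .CAND_COLS, drop = FALSE])
}

#' @describeIn IndelCandidates number of candidates
#' @param x an `IndelCandidates` object
#' @export
setMethod("length", "IndelCandidates", function(x) nrow(x@data))

setMethod("show", "IndelCandidates", function(object) {
    d <- object@data
    cat("IndelCandidates with", nrow(d), "candidates\n")
    if (nrow(d)) {
        pass <- d$filtersFailed == ""
        cat(sprintf("  PASS: %d  (deletions %d, insertions %d, unresolved %d)\n",
                    sum(pass),
                    sum(d$callType == "deletion"),
                    sum(d$callType == "insertion"),
                    sum(d$callType == "unresolved")))
    }
})

#' Extract the candidate table
#'
#' @param x an `IndelCandidates` object
#' @return a `data.frame`, one row per candidate.
#' @export
candidateTable <- function(x) {
    stopifnot(is(x, "IndelCandidates"))
    as.data.frame(x@data)
}

#' PASS candidates (no failed filters, resolved call)
#'
#' @param x an `IndelCandidates` object annotated by [applyFilters()]
#' @return a `data.frame` of candidates failing no filter.
#' @export
passCandidates <- function(x) {
    d <- candidateTable(x)
    d[d$filtersFailed == "", , drop = FALSE]
}
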