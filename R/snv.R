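## Companion single-base variant caller: pileup of aligned (non-clipped)
## bases, threshold calling (depth >= 3, alternate fraction strictly > 0.75),
## known-polymorphism exclusion, cross-sample recurrence filtering, and
## synonymous/non-synonymous classification against a CDS annotation.

#' Pileup of aligned bases
#' Counts A/C/G/T/N per covered reference position.  Only aligned bases
#' contribute: soft-clipped bases are excluded, and alignments whose CIGAR
#' carries internal indel operators are skipped (their bases cannot be
#' placed per-position by this alignment model; their span still counts for
#' breakpoint coverage, but not here).
#'
#' @param x a (filtered) [PartialAlignments-class] object
#' @return a `data.frame` with columns `seqname`, `pos`, `A`, `C`, `G`,
#'   `T`, `N`, `depth`, one row per covered position, sorted.
#' @import data.table
#' @export
pileupCounts <- function(x) {
    d <- x@data
    d <- d[!d$hasIndelOps, , drop = FALSE]
    emptyPile <- data.frame(seqname = character(), pos = integer(),
                            A = integer(), C = integer(), G = integer(),
                            T = integer(), N = integer(), depth = integer(),
                            stringsAsFactors = FALSE)
    if (nrow(d) == 0L) return(emptyPile)
    span <- d$end - d$start + 1L
    alnSeq <- substr(d$seq, d$leftClip + 1L, d$leftClip + span)
    pos <- unlist(Map(seq.int, d$start, d$end), use.names = FALSE)
    base <- unlist(strsplit(alnSeq, "", fixed = TRUE), use.names = FALSE)
    dt <- data.table::data.table(
        seqname = rep(d$seqname, span), pos = pos, base = base)
    counts <- dt[, .N, by = c("seqname", "pos", "base")]
    wide <- data.table::dcast(counts, seqname + pos ~ base,
                              value.var = "N", fill = 0L)
    for (b in c("A", "C", "G", "T", "N"))
        if (is.null(wide[[b]])) wide[[b]] <- 0L
    extra <- setdiff(colnames(wide), c("seqname", "pos", "A", "C", "G",
                                       "T", "N"))
    if (length(extra)) wide[, (extra) := NULL]
    out <- as.data.frame(wide)[, c("seqname", "pos", "A", "C", "G", "T",
                                   "N")]
    out$depth <- out$A + out$C + out$G + out$T + out$N
    out[order(out$seqname, out$pos, method = "radix"), , drop = FALSE]
}

#' Call single-base variants from a pileup
#'
#' A candidate is emitted iff depth >= `minDepth` and the most frequent
#' non-reference base (A/C/G/T; N is never an alternate but does count in
#' the depth denominator) has fraction strictly greater than `minFraction`.
#' At most one candidate per position; a tie between two alternate bases
#' yields no call.
#'
#' @param pile a pileup data.frame from [pileupCounts()]
#' @param reference DNAStringSet
#' @param minDepth minimum read depth (default 3, inclusive)
#' @param minFraction alternate-fraction threshold (default 0.75, strict)
#' @param sample sample identifier carried into the output
#' @return a `data.frame` with columns `sample`, `seqname`, `pos`, `ref`,
#'   `alt`, `depth`, `altCount`, `fraction`.
#' @export
callSnvs <- function(pile, reference, minDepth = 3L, minFraction = 0.75,
                     sample = "sample1") {
    empty <- data.frame(sample = character(), seqname = character(),
                        pos = integer(), ref = character(),
                        alt = character(), depth = integer(),
                        altCount = integer(), fraction = numeric(),
                        stringsAsFactors = FALSE)
    if (nrow(pile) == 0L) return(empty)
    pile <- pile[pile$depth >= minDepth, , drop = FALSE]
    if (nrow(pile) == 0L) return(empty)
    rows <- vector("list", nrow(pile))
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(nrow(pile))) {
        sn <- pile$seqname[i]; p <- pile$pos[i]
        ref <- as.character(Biostrings::subseq(reference[[sn]], p, p))
        altBases <- setdiff(bases, ref)
        cnt <- unlist(pile[i, altBases])
        top <- max(cnt)
        if (top == 0L) next
        if (sum(cnt == top) > 1L) next          # tied alternates: no call
        frac <- top / pile$depth[i]
        if (frac <= minFraction) next
        rows[[i]] <- data.frame(
            sample = sample, seqname = sn, pos = p, ref = ref,
            alt = altBases[which.max(cnt)], depth = pile$depth[i],
            altCount = as.integer(top), fraction = frac,
            stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Read a CDS annotation table
#'
#' Six-column TSV: seqname, start (0-based), end (exclusive), strand
#' (+/-), frame (0/1/2: bases to skip to reach the first complete codon),
#' gene.  Returned 1-based inclusive.
#'
#' @param file path to the TSV (no header)
#' @param reference optional DNAStringSet for bounds validation
#' @return a `data.frame` with columns `seqname`, `start`, `end`, `strand`,
#'   `frame`, `gene`.
#' @export
readCdsAnnotation <- function(file, reference = NULL) {
    d <- utils::read.table(file, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("seqname", "start", "end",
                                         "strand", "frame", "gene"))
    d$start <- d$start + 1L                    # 0-based half-open -> 1-based
    if (any(d$end < d$start)) stop("empty CDS interval in ", file)
    if (!all(d$strand %in% c("+", "-"))) stop("invalid strand in ", file)
    if (!all(d$frame %in% 0:2)) stop("frame must be 0, 1 or 2 in ", file)
    if (!is.null(reference)) {
        lens <- referenceLengths(reference)
        bad <- !(d$seqname %in% names(lens)) | d$start < 1L |
            d$end > lens[d$seqname]
        if (any(bad)) stop(sum(bad), " CDS interval(s) outside reference")
    }
    d
}

## Codon positions (genomic, in translation order) containing `pos` within
## one CDS interval, or NULL when the codon is truncated by the interval.
.codonAt <- function(cds, pos) {
    if (cds$strand == "+") {
        off <- pos - cds$start - cds$frame
        if (off < 0L) return(NULL)
        first <- cds$start + cds$frame + 3L * (off %/% 3L)
        codon <- first + 0:2
        if (codon[3] > cds$end) return(NULL)
    } else {
        off <- cds$end - cds$frame - pos
        if (off < 0L) return(NULL)
        first <- cds$end - cds$frame - 3L * (off %/% 3L)
        codon <- first - (0:2)
        if (codon[3] < cds$start) return(NULL)
    }
    codon
}

#' Classify single-base candidates as synonymous or non-synonymous
#'
#' Translates the codon containing each candidate position with and without
#' the alternate base, strand- and frame-aware, using the standard nuclear
#' genetic code.  Positions outside all CDS intervals are `"noncoding"`;
#' codons truncated by an interval end give `"unknown"`.
#'
#' @param snvs a data.frame from [callSnvs()]
#' @param cds a CDS annotation data.frame from [readCdsAnnotation()], or
#'   NULL (everything becomes `"unknown"`)
#' @param reference DNAStringSet
#' @return `snvs` with a `consequence` column appended (`"synonymous"`,
#'   `"nonsynonymous"`, `"noncoding"`, `"unknown"`).
#' @export
annotateConsequence <- function(snvs, cds, reference) {
    if (nrow(snvs) == 0L) {
        snvs$consequence <- character(0)
        return(snvs)
    }
    if (is.null(cds)) {
        snvs$consequence <- "unknown"
        return(snvs)
    }
    translateCodon <- function(s) {
        ## no.init.codon: a lone codon must not be treated as an initiator
        as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           no.init.codon = TRUE))
    }
    csq <- character(nrow(snvs))
    for (i in seq_len(nrow(snvs))) {
        p <- snvs$pos[i]; sn <- snvs$seqname[i]
        hit <- which(cds$seqname == sn & cds$start <= p & cds$end >= p)
        if (!length(hit)) { csq[i] <- "noncoding"; next }
        cdsRow <- cds[hit[1], , drop = FALSE]
        codon <- .codonAt(cdsRow, p)
        if (is.null(codon)) { csq[i] <- "unknown"; next }
        bases <- vapply(codon, function(q) as.character(
            Biostrings::subseq(reference[[sn]], q, q)), character(1))
        altBases <- bases
        altBases[match(p, codon)] <- snvs$alt[i]
        if (cdsRow$strand == "-") {
            comp <- function(b) chartr("ACGTN", "TGCAN", b)
            bases <- comp(bases); altBases <- comp(altBases)
        }
        aaRef <- translateCodon(paste(bases, collapse = ""))
        aaAlt <- translateCodon(paste(altBases, collapse = ""))
        csq[i] <- if (aaRef == aaAlt) "synonymous" else "nonsynonymous"
    }
    snvs$consequence <- csq
    snvs
}

#' Multi-sample single-base calling pipeline
#'
#' Per sample: pileup, threshold calling, exclusion of known polymorphic
#' positions (exact position match).  Across samples: recurrence filtering
#' (candidates at a position carried by more than `maxSamples` samples are
#' systematic artifacts and removed everywhere).  Optionally restricts the
#' output to non-synonymous changes.
#'
#' @param alignmentsList named list of (filtered)
#'   [PartialAlignments-class] objects, one per sample
#' @param reference DNAStringSet
#' @param cds optional CDS annotation ([readCdsAnnotation()])
#' @param known optional width-1 GRanges of known polymorphic positions
#' @param minDepth,minFraction see [callSnvs()]
#' @param maxSamples recurrence bound (default 2: keep candidates seen in
#'   fewer than 3 samples)
#' @param nonsynonymousOnly restrict output to non-synonymous candidates
#'   (requires `cds`)
#' @return named list of candidate data.frames, one per sample.
#' @export
snvPipeline <- function(alignmentsList, reference, cds = NULL, known = NULL,
                        minDepth = 3L, minFraction = 0.75, maxSamples = 2L,
                        nonsynonymousOnly = FALSE) {
    if (nonsynonymousOnly && is.null(cds))
        stop("nonsynonymousOnly requires a CDS annotation")
    samples <- names(alignmentsList)
    if (is.null(samples))
        samples <- paste0("sample", seq_along(alignmentsList))
    calls <- lapply(seq_along(alignmentsList), function(i) {
        snvs <- callSnvs(pileupCounts(alignmentsList[[i]]), reference,
                         minDepth = minDepth, minFraction = minFraction,
                         sample = samples[i])
        if (!is.null(known) && length(known) && nrow(snvs)) {
            kn <- paste(as.character(GenomicRanges::seqnames(known)),
                        GenomicRanges::start(known))
            snvs <- snvs[!(paste(snvs$seqname, snvs$pos) %in% kn), ,
                         drop = FALSE]
        }
        snvs
    })
    names(calls) <- samples
    calls <- crossSampleFilter(calls, maxSamples = maxSamples,
                               posColumn = "pos", annotate = FALSE)
    calls <- lapply(calls, annotateConsequence, cds = cds,
                    reference = reference)
    if (nonsynonymousOnly)
        calls <- lapply(calls, function(d)
            d[d$consequence == "nonsynonymous", , drop = FALSE])
    calls
}
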