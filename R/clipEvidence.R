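## Core breakpoint evidence: clip-site collection, the Jaccard-style r
## statistic, clipped-tail consensus, and insertion/deletion classification.
##
## Conventions: a RIGHT clip sits at higher reference coordinates than its
## aligned span; its breakpoint p is the LAST aligned base and the neighbour
## is p+1.  A LEFT clip's breakpoint is the FIRST aligned base; neighbour
## p-1.  Clipped tails are always stored OUTWARD from p, so index i of a
## tail corresponds to reference offset i beyond p in the clip direction
## (for LEFT tails this means the stored string is the clip reversed).

#' Apply the mapping filter stack to alignments
#'
#' Keeps uniquely mapped alignments with at most `maxMismatches` mismatches
#' whose clipped ends do not exceed `maxClipFraction` of the read length.
#' Alignments with internal indel operators are retained (their indel is the
#' mapper's call); downstream evidence collection skips them unless asked.
#'
#' @param x a [PartialAlignments-class] object
#' @param maxMismatches maximum mismatch count (default 2)
#' @param maxClipFraction maximum clip length as a fraction of read length
#'   (default 0.2)
#' @return the filtered `PartialAlignments`.
#' @export
filterAlignments <- function(x, maxMismatches = 2L, maxClipFraction = 0.2) {
    d <- x@data
    if (nrow(d) == 0L) return(x)
    readLen <- nchar(d$seq)
    maxClip <- floor(maxClipFraction * readLen)
    keep <- d$isUnique &
        (is.na(d$mismatches) | d$mismatches <= maxMismatches) &
        d$leftClip <= maxClip & d$rightClip <= maxClip
    x[keep]
}

#' Collect clip events from partially mapped reads
#'
#' One event per clipped read end: a read clipped at both ends contributes
#' two events.  Tails are stored outward from the breakpoint (LEFT tails
#' reversed).  Alignments with internal indel operators are skipped unless
#' `countMapperIndels` is set.
#'
#' @param x a filtered [PartialAlignments-class] object
#' @param countMapperIndels also emit events from reads whose CIGAR carries
#'   internal I/D operators (default FALSE)
#' @return a `data.frame` with columns `seqname`, `p`, `direction`
#'   (`"right"`/`"left"`), `readId`, `clipSeq`.
#' @export
collectClipEvents <- function(x, countMapperIndels = FALSE) {
    d <- x@data
    use <- if (countMapperIndels) rep(TRUE, nrow(d)) else !d$hasIndelOps
    d <- d[use, , drop = FALSE]
    out <- list()
    ri <- which(d$rightClip > 0L)
    if (length(ri)) {
        len <- nchar(d$seq[ri])
        out$right <- data.frame(
            seqname = d$seqname[ri],
            p = d$end[ri],
            direction = "right",
            readId = d$readId[ri],
            clipSeq = substr(d$seq[ri], len - d$rightClip[ri] + 1L, len),
            stringsAsFactors = FALSE)
    }
    li <- which(d$leftClip > 0L)
    if (length(li)) {
        out$left <- data.frame(
            seqname = d$seqname[li],
            p = d$start[li],
            direction = "left",
            readId = d$readId[li],
            clipSeq = .revStr(substr(d$seq[li], 1L, d$leftClip[li])),
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(seqname = character(), p = integer(),
                          direction = character(), readId = character(),
                          clipSeq = character(), stringsAsFactors = FALSE))
    ev <- do.call(rbind, out)
    rownames(ev) <- NULL
    ev[order(ev$seqname, ev$p, ev$direction, ev$readId, method = "radix"), ,
       drop = FALSE]
}

.revStr <- function(s) {
    vapply(strsplit(s, "", fixed = TRUE),
           function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Breakpoint read-set counts and the r statistic
#'
#' For each site (sequence, p, direction) computes N(p) = reads whose
#' aligned span covers p, N(p+/-1) = reads covering the neighbour in the
#' clip direction, N(both) = reads covering both, and
#' r = N(both) / (N(p) + N(p+/-1) - N(both)) -- the Jaccard index of the
#' two read sets.  r is defined as 1 when both sets are empty (no evidence
#' of a breakpoint).  Clipped bases never count as coverage.
#'
#' @param x a [PartialAlignments-class] object
#' @param sites a data.frame with columns `seqname`, `p`, `direction`
#' @param seqlengths named integer vector of reference lengths (used to flag
#'   sites whose neighbour falls outside the reference)
#' @return `sites` with columns `Np`, `Npm1`, `Nboth`, `r`, `evaluable`
#'   appended.  Sites with an out-of-bounds neighbour have `evaluable =
#'   FALSE` and NA counts.
#' @export
siteCounts <- function(x, sites, seqlengths = NULL) {
    d <- x@data
    sites <- as.data.frame(sites)
    stopifnot(all(c("seqname", "p", "direction") %in% colnames(sites)))
    n <- nrow(sites)
    q <- ifelse(sites$direction == "right", sites$p + 1L, sites$p - 1L)
    evaluable <- q >= 1L
    if (!is.null(seqlengths))
        evaluable <- evaluable &
            q <= seqlengths[sites$seqname] &
            sites$p <= seqlengths[sites$seqname] & sites$p >= 1L
    Np <- Npm1 <- Nboth <- rep(NA_integer_, n)
    for (sn in unique(sites$seqname)) {
        si <- which(sites$seqname == sn & evaluable)
        if (!length(si)) next
        spans <- IRanges::IRanges(start = d$start[d$seqname == sn],
                                  end = d$end[d$seqname == sn])
        Np[si] <- IRanges::countOverlaps(
            IRanges::IRanges(sites$p[si], width = 1L), spans)
        Npm1[si] <- IRanges::countOverlaps(
            IRanges::IRanges(q[si], width = 1L), spans)
        lo <- pmin(sites$p[si], q[si]); hi <- pmax(sites$p[si], q[si])
        Nboth[si] <- IRanges::countOverlaps(
            IRanges::IRanges(lo, hi), spans, type = "within")
    }
    denom <- Np + Npm1 - Nboth
    r <- ifelse(denom == 0L, 1, Nboth / denom)
    cbind(sites, Np = Np, Npm1 = Npm1, Nboth = Nboth, r = r,
          evaluable = evaluable)
}

#' Consensus of the clipped tails at one breakpoint
#'
#' Per-offset plurality over the tails, truncated at the first offset where
#' fewer than `minSupport` tails still extend or where the plurality
#' fraction (among extending tails) drops below `agreement`.  Base ties are
#' broken lexicographically for determinism.
#'
#' @param clipSeqs character vector of clipped tails, all stored outward
#'   from the same breakpoint
#' @param agreement minimum plurality fraction to extend (default 0.5)
#' @param minSupport minimum number of tails that must still extend
#'   (default 1)
#' @return a list with `consensus` (character), `support` (number of tails),
#'   and `agreement` (per-base plurality fractions).
#' @export
gapConsensus <- function(clipSeqs, agreement = 0.5, minSupport = 1L) {
    stopifnot(length(clipSeqs) >= 1L)
    lens <- nchar(clipSeqs)
    maxLen <- max(lens)
    cons <- character(0)
    agree <- numeric(0)
    for (i in seq_len(maxLen)) {
        ext <- lens >= i
        if (sum(ext) < minSupport) break
        bases <- substr(clipSeqs[ext], i, i)
        tab <- table(bases)
        top <- max(tab)
        frac <- top / sum(ext)
        if (frac < agreement) break
        winner <- sort(names(tab)[tab == top])[1]
        cons <- c(cons, winner)
        agree <- c(agree, frac)
    }
    list(consensus = paste(cons, collapse = ""),
         support = length(clipSeqs),
         agreement = agree)
}

## Reference bases outward from p in the clip direction, as a string whose
## index i is reference offset i beyond p.  LEFT direction reads leftward,
## so the returned string is reversed genomic sequence.
.refOutward <- function(reference, seqname, p, direction, n) {
    len <- Biostrings::width(reference)[match(seqname, names(reference))]
    if (direction == "right") {
        from <- p + 1L; to <- min(p + n, len)
        if (from > to) return("")
        as.character(Biostrings::subseq(reference[[seqname]], from, to))
    } else {
        to <- p - 1L; from <- max(p - n, 1L)
        if (from > to) return("")
        .revStr(as.character(
            Biostrings::subseq(reference[[seqname]], from, to)))
    }
}

.matchCount <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    if (n == 0L) return(c(matches = 0L, span = 0L))
    c(matches = sum(utf8ToInt(substr(a, 1L, n)) ==
                        utf8ToInt(substr(b, 1L, n))),
      span = n)
}

#' Classify a breakpoint consensus as insertion, deletion, or unresolved
#'
#' Scans three hypothesis families against the reference continuation
#' beyond the breakpoint, in the clip direction: a deletion of d bases
#' (consensus should match the reference d bases further out), an insertion
#' of i bases (consensus after its first i bases should match the reference
#' continuation, the skipped bases being the inserted sequence), and the
#' null hypothesis (consensus matches the continuation directly, i.e. the
#' clip is noise).  The winning hypothesis maximises per-base identity over
#' the compared span, requiring identity >= `identityMin` and span >=
#' `minSpan`; ties prefer the larger compared span, then the smaller
#' hypothesis length (null counts as 0), then deletion before insertion.
#' A winning null hypothesis, or no qualifying hypothesis, yields
#' `"unresolved"`.
#'
#' @param consensus consensus string from [gapConsensus()], outward from p
#' @param reference DNAStringSet
#' @param seqname,p,direction breakpoint site
#' @param maxIndelLength largest indel length considered (default 9)
#' @param identityMin minimum per-base identity (default 0.9)
#' @param minSpan minimum compared span in bases (default 2)
#' @param minLength minimum consensus length to attempt classification
#'   (default 4)
#' @return a list with `type` (`"deletion"`, `"insertion"`,
#'   `"unresolved"`), `length`, `varSeq` (genomic orientation: deleted
#'   reference bases or inserted bases), `variantStart` (genomic start of
#'   the deleted span, or the base after which insertion occurs), and
#'   `identity`.
#' @export
classifyIndel <- function(consensus, reference, seqname, p, direction,
                          maxIndelLength = 9L, identityMin = 0.9,
                          minSpan = 2L, minLength = 4L) {
    unres <- list(type = "unresolved", length = NA_integer_,
                  varSeq = NA_character_, variantStart = NA_integer_,
                  identity = NA_real_)
    cl <- nchar(consensus)
    if (cl < minLength) return(unres)
    refOut <- .refOutward(reference, seqname, p, direction,
                          maxIndelLength + cl)
    hyp <- list()
    ## null: consensus vs direct continuation
    m <- .matchCount(consensus, refOut)
    hyp[[length(hyp) + 1L]] <- c(type = 0, len = 0, m)
    ## deletion of d: consensus vs continuation d further out
    for (d in seq_len(maxIndelLength)) {
        if (nchar(refOut) <= d) break
        m <- .matchCount(consensus, substr(refOut, d + 1L, nchar(refOut)))
        hyp[[length(hyp) + 1L]] <- c(type = 1, len = d, m)
    }
    ## insertion of i: consensus minus its first i bases vs continuation
    for (i in seq_len(min(maxIndelLength, cl - 1L))) {
        m <- .matchCount(substr(consensus, i + 1L, cl), refOut)
        hyp[[length(hyp) + 1L]] <- c(type = 2, len = i, m)
    }
    h <- do.call(rbind, hyp)
    identity <- ifelse(h[, "span"] > 0, h[, "matches"] / h[, "span"], 0)
    ok <- h[, "span"] >= minSpan & identity >= identityMin
    if (!any(ok)) return(unres)
    h <- h[ok, , drop = FALSE]; identity <- identity[ok]
    ord <- order(-identity, -h[, "span"], h[, "len"], h[, "type"])
    best <- ord[1]
    if (h[best, "type"] == 0) return(unres)
    len <- as.integer(h[best, "len"])
    if (h[best, "type"] == 1) {       # deletion
        vs <- if (direction == "right") p + 1L else p - len
        varSeq <- as.character(Biostrings::subseq(
            reference[[seqname]], vs, vs + len - 1L))
        list(type = "deletion", length = len, varSeq = varSeq,
             variantStart = vs, identity = identity[best])
    } else {                          # insertion
        out <- substr(consensus, 1L, len)
        varSeq <- if (direction == "right") out else .revStr(out)
        anchor <- if (direction == "right") p else p - 1L
        list(type = "insertion", length = len, varSeq = varSeq,
             variantStart = anchor, identity = identity[best])
    }
}

#' Evaluate all clip sites and produce unfiltered indel candidates
#'
#' Every (sequence, p, direction) with at least one clip event is evaluated,
#' except exact target start/end positions (artifact-prone capture
#' boundaries).  Left- and right-direction candidates whose resolved calls
#' imply the same variant (same type and length, implied variant start
#' within `mergeTolerance`) are merged into one candidate with summed
#' support; the representative row is the direction with more support.
#'
#' @param x filtered [PartialAlignments-class]
#' @param reference DNAStringSet
#' @param targets optional GRanges of capture targets
#' @param sample sample identifier carried into the candidate table
#' @param countMapperIndels see [collectClipEvents()]
#' @param consensusAgreement,minConsensusSupport see [gapConsensus()]
#' @param maxIndelLength,identityMin,minSpan,minLength see [classifyIndel()]
#' @param mergeTolerance maximum distance between implied variant starts for
#'   two directions to merge (default `maxIndelLength`)
#' @return an [IndelCandidates-class] object (filters not yet applied).
#' @export
callCandidates <- function(x, reference, targets = NULL, sample = "sample1",
                           countMapperIndels = FALSE,
                           consensusAgreement = 0.5,
                           minConsensusSupport = 1L,
                           maxIndelLength = 9L, identityMin = 0.9,
                           minSpan = 2L, minLength = 4L,
                           mergeTolerance = maxIndelLength) {
    ev <- collectClipEvents(x, countMapperIndels = countMapperIndels)
    if (nrow(ev) == 0L) return(IndelCandidates())
    sites <- unique(ev[, c("seqname", "p", "direction")])
    if (!is.null(targets) && length(targets)) {
        bnd <- paste(as.character(GenomicRanges::seqnames(targets)),
                     c(GenomicRanges::start(targets),
                       GenomicRanges::end(targets)))
        sites <- sites[!(paste(sites$seqname, sites$p) %in% bnd), ,
                       drop = FALSE]
    }
    if (nrow(sites) == 0L) return(IndelCandidates())
    lens <- referenceLengths(reference)
    sc <- siteCounts(x, sites, seqlengths = lens)
    sc <- sc[sc$evaluable, , drop = FALSE]
    if (nrow(sc) == 0L) return(IndelCandidates())

    evKey <- paste(ev$seqname, ev$p, ev$direction)
    rows <- vector("list", nrow(sc))
    for (i in seq_len(nrow(sc))) {
        key <- paste(sc$seqname[i], sc$p[i], sc$direction[i])
        tails <- ev$clipSeq[evKey == key]
        cons <- gapConsensus(tails, agreement = consensusAgreement,
                             minSupport = minConsensusSupport)
        call <- classifyIndel(cons$consensus, reference, sc$seqname[i],
                              sc$p[i], sc$direction[i],
                              maxIndelLength = maxIndelLength,
                              identityMin = identityMin,
                              minSpan = minSpan, minLength = minLength)
        rows[[i]] <- data.frame(
            sample = sample, seqname = sc$seqname[i], p = sc$p[i],
            direction = sc$direction[i], Np = sc$Np[i], Npm1 = sc$Npm1[i],
            Nboth = sc$Nboth[i], r = sc$r[i], support = cons$support,
            consensus = cons$consensus,
            minAgreement = if (length(cons$agreement))
                min(cons$agreement) else NA_real_,
            callType = call$type,
            callLength = if (is.na(call$length)) NA_integer_ else
                call$length,
            callSeq = if (is.na(call$varSeq)) "" else call$varSeq,
            variantStart = call$variantStart,
            identity = call$identity,
            mergedDirections = sc$direction[i],
            filtersFailed = "",
            stringsAsFactors = FALSE)
    }
    cand <- do.call(rbind, rows)
    cand <- .mergeDirections(cand, mergeTolerance)
    cand <- cand[order(cand$seqname, cand$p, cand$direction,
                       method = "radix"), , drop = FALSE]
    rownames(cand) <- NULL
    IndelCandidates(cand)
}

## Merge resolved candidates implying the same variant from opposite clip
## directions.  Greedy clustering of variantStart within tolerance per
## (seqname, type, length) group.
.mergeDirections <- function(cand, tolerance) {
    res <- cand$callType != "unresolved"
    keep <- cand[!res, , drop = FALSE]
    cc <- cand[res, , drop = FALSE]
    if (nrow(cc) <= 1L) return(rbind(keep, cc))
    grp <- paste(cc$seqname, cc$callType, cc$callLength)
    merged <- list()
    for (g in unique(grp)) {
        gi <- which(grp == g)
        gi <- gi[order(cc$variantStart[gi])]
        cluster <- gi[1]
        for (j in gi[-1]) {
            if (cc$variantStart[j] - cc$variantStart[cluster[length(cluster)]]
                <= tolerance) {
                cluster <- c(cluster, j)
            } else {
                merged[[length(merged) + 1L]] <- .collapseCluster(cc, cluster)
                cluster <- j
            }
        }
        merged[[length(merged) + 1L]] <- .collapseCluster(cc, cluster)
    }
    rbind(keep, do.call(rbind, merged))
}

.collapseCluster <- function(cc, idx) {
    if (length(idx) == 1L) return(cc[idx, , drop = FALSE])
    rep_i <- idx[order(-cc$support[idx],
                       cc$direction[idx] != "right")][1]
    row <- cc[rep_i, , drop = FALSE]
    row$support <- sum(cc$support[idx])
    row$mergedDirections <- paste(sort(unique(cc$direction[idx])),
                                  collapse = "+")
    row
}
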