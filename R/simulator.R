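## Synthetic-data generator: multi-target reference, planted indels/SNVs,
## ~50 nt single-end reads at ~40x with ~1% base error, and a deterministic
## emulation of an end-gapped mapper in which read tails crossing an indel
## breakpoint become soft clips of at most 20% of the read length.  All
## randomness flows through R's RNG: set.seed() before calling, or pass
## `seed` to simulateDataset(), for byte-reproducible output.

#' Simulation configuration
#'
#' Defaults emulate the targeted exome-capture study design this package is
#' built around: 50 nt single-end reads at a mean depth of 42 per base with
#' a 1% per-base error rate over a multi-target reference, 12 samples, and
#' end clips capped at 20% of the read length.
#'
#' @param refLength total reference length in bases
#' @param nTargets number of capture targets
#' @param targetLengthRange integer range of target lengths
#' @param readLength read length in bases
#' @param meanDepth mean per-base depth over each target
#' @param errorRate per-base error probability in `[0, 1)`
#' @param nSamples number of samples
#' @param maxClipFraction maximum clip as a fraction of read length
#' @param seqname reference sequence name
#' @return a validated list of simulation parameters.
#' @export
simConfig <- function(refLength = 100000L, nTargets = 20L,
                      targetLengthRange = c(250L, 350L), readLength = 50L,
                      meanDepth = 42, errorRate = 0.01, nSamples = 12L,
                      maxClipFraction = 0.2, seqname = "ref1") {
    stopifnot(errorRate >= 0, errorRate < 1,
              readLength >= 20L, meanDepth > 0, nSamples >= 1L,
              length(targetLengthRange) == 2L,
              targetLengthRange[1] <= targetLengthRange[2])
    list(refLength = as.integer(refLength), nTargets = as.integer(nTargets),
         targetLengthRange = as.integer(targetLengthRange),
         readLength = as.integer(readLength), meanDepth = meanDepth,
         errorRate = errorRate, nSamples = as.integer(nSamples),
         maxClipFraction = maxClipFraction, seqname = seqname)
}

#' Simulate a multi-target reference
#'
#' Uniform random A/C/G/T sequence with non-overlapping targets, each
#' flanked by at least one read length of non-target sequence (so reads
#' sampled over the padded span cover target edges).
#'
#' @param config a list from [simConfig()]
#' @return a list with `reference` (DNAStringSet) and `targets` (GRanges
#'   with `label` metadata).
#' @export
simulateReference <- function(config = simConfig()) {
    lens <- config$targetLengthRange[1] - 1L +
        sample.int(config$targetLengthRange[2] -
                       config$targetLengthRange[1] + 1L,
                   config$nTargets, replace = TRUE)
    minGap <- config$readLength
    needed <- sum(lens) + (config$nTargets + 1L) * minGap
    if (needed > config$refLength)
        stop("targets do not fit: need ", needed, " > ", config$refLength,
             " reference bases")
    leftover <- config$refLength - needed
    extra <- as.vector(stats::rmultinom(1, leftover,
                                        rep(1, config$nTargets + 1L)))
    gaps <- minGap + extra
    starts <- integer(config$nTargets)
    at <- 0L
    for (i in seq_len(config$nTargets)) {
        at <- at + gaps[i]
        starts[i] <- at + 1L
        at <- at + lens[i]
    }
    seq <- paste(sample(c("A", "C", "G", "T"), config$refLength,
                        replace = TRUE), collapse = "")
    reference <- Biostrings::DNAStringSet(seq)
    names(reference) <- config$seqname
    targets <- GenomicRanges::GRanges(
        config$seqname,
        IRanges::IRanges(start = starts, width = lens))
    S4Vectors::mcols(targets)$label <-
        paste0("exon", seq_len(config$nTargets))
    list(reference = reference, targets = targets)
}

#' Plant variants into targets
#'
#' Chooses positions for the requested variants inside targets, at least
#' `margin` bases from any target boundary (so the boundary exclusion never
#' touches a planted variant) and at least `isolation` bases apart (so
#' recovery scoring is unambiguous).  SNV alternates and inserted sequences
#' are drawn at random; deleted sequences are the reference bases removed.
#'
#' @param reference DNAStringSet from [simulateReference()]
#' @param targets GRanges from [simulateReference()]
#' @param variants data.frame with columns `type` (`"SNV"`, `"INS"`,
#'   `"DEL"`), `length` (1 for SNV), and `samples` (comma-separated sample
#'   indices, e.g. `"1"` or `"1,2,5"`, or `"all"`)
#' @param config a list from [simConfig()]
#' @param margin minimum distance from target boundaries (default 15)
#' @param isolation minimum distance between variants (default 2 read
#'   lengths)
#' @param maxTries placement attempts per variant before giving up
#' @return the truth set: a data.frame with columns `seqname`, `pos`
#'   (1-based; deletion start / base preceding an insertion / SNV
#'   position), `type`, `length`, `seq`, `samples`.
#' @export
plantVariants <- function(reference, targets, variants,
                          config = simConfig(), margin = 15L,
                          isolation = 2L * config$readLength,
                          maxTries = 200L) {
    stopifnot(all(variants$type %in% c("SNV", "INS", "DEL")),
              all(variants$length >= 1L), all(variants$length <= 9L),
              all(variants$length[variants$type == "SNV"] == 1L))
    sn <- as.character(GenomicRanges::seqnames(targets))
    ts <- GenomicRanges::start(targets)
    te <- GenomicRanges::end(targets)
    placed <- integer(0)
    rows <- vector("list", nrow(variants))
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(nrow(variants))) {
        L <- as.integer(variants$length[i])
        type <- variants$type[i]
        ok <- FALSE
        for (try in seq_len(maxTries)) {
            t <- sample(length(targets), 1L)
            lo <- ts[t] + margin
            hi <- te[t] - margin - (if (type == "DEL") L else 0L)
            if (hi < lo) next
            pos <- lo - 1L + sample.int(hi - lo + 1L, 1L)
            if (length(placed) && min(abs(placed - pos)) < isolation) next
            ok <- TRUE
            break
        }
        if (!ok)
            stop("could not place variant ", i,
                 " under the isolation constraint")
        placed <- c(placed, pos)
        seqname <- sn[t]
        if (type == "SNV") {
            ref <- as.character(Biostrings::subseq(reference[[seqname]],
                                                   pos, pos))
            vseq <- sample(setdiff(bases, ref), 1L)
        } else if (type == "DEL") {
            vseq <- as.character(Biostrings::subseq(reference[[seqname]],
                                                    pos, pos + L - 1L))
        } else {
            vseq <- paste(sample(bases, L, replace = TRUE), collapse = "")
        }
        smp <- as.character(variants$samples[i])
        if (smp == "all")
            smp <- paste(seq_len(config$nSamples), collapse = ",")
        rows[[i]] <- data.frame(
            seqname = seqname, pos = pos, type = type, length = L,
            seq = vseq, samples = smp, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    truth[order(truth$seqname, truth$pos, method = "radix"), ,
          drop = FALSE]
}

.sampleSet <- function(s) as.integer(strsplit(s, ",")[[1]])

.variantsFor <- function(truth, sampleIdx) {
    keep <- vapply(truth$samples, function(s) sampleIdx %in% .sampleSet(s),
                   logical(1))
    truth[keep, , drop = FALSE]
}

## hap = ref + shift; shifts are independent in reference coordinates.
.refToHap <- function(pos, vars) {
    shift <- 0L
    for (j in seq_len(nrow(vars))) {
        if (vars$type[j] == "INS" && pos > vars$pos[j])
            shift <- shift + vars$length[j]
        else if (vars$type[j] == "DEL" && pos >= vars$pos[j] + vars$length[j])
            shift <- shift - vars$length[j]
    }
    pos + shift
}

## Inverse map for haplotype positions outside inserted/deleted material.
.hapToRef <- function(h, vars) {
    delta <- 0L
    for (j in seq_len(nrow(vars))) {
        if (vars$type[j] == "DEL") {
            hB <- (vars$pos[j] - 1L) - delta
            if (h > hB) delta <- delta + vars$length[j] else break
        } else if (vars$type[j] == "INS") {
            hI <- vars$pos[j] - delta
            if (h > hI + vars$length[j]) delta <- delta - vars$length[j]
            else break
        }
    }
    h + delta
}

#' Build one sample's haplotype sequence
#'
#' Applies the sample's planted variants to the reference.  Round trip with
#' the truth set: the haplotype differs from the reference by exactly the
#' planted variants.
#'
#' @param reference DNAStringSet
#' @param truth truth set from [plantVariants()]
#' @param sampleIdx sample index (1-based)
#' @return named character vector, one element per reference sequence.
#' @export
buildHaplotype <- function(reference, truth, sampleIdx) {
    vars <- .variantsFor(truth, sampleIdx)
    out <- stats::setNames(as.character(reference), names(reference))
    for (sn in unique(vars$seqname)) {
        v <- vars[vars$seqname == sn, , drop = FALSE]
        v <- v[order(-v$pos), , drop = FALSE]      # apply right to left
        s <- out[[sn]]
        for (j in seq_len(nrow(v))) {
            if (v$type[j] == "SNV") {
                substr(s, v$pos[j], v$pos[j]) <- v$seq[j]
            } else if (v$type[j] == "DEL") {
                s <- paste0(substr(s, 1L, v$pos[j] - 1L),
                            substr(s, v$pos[j] + v$length[j], nchar(s)))
            } else {
                s <- paste0(substr(s, 1L, v$pos[j]), v$seq[j],
                            substr(s, v$pos[j] + 1L, nchar(s)))
            }
        }
        out[[sn]] <- s
    }
    out
}

#' Sample reads from a haplotype
#'
#' Read starts are uniform over each target's padded span (one read length
#' of flank on each side), with Poisson counts giving expected per-base
#' depth `meanDepth`.  Each base is flipped to a uniformly chosen other
#' base with probability `errorRate`; strands are equiprobable.
#'
#' @param haplotype named character vector from [buildHaplotype()]
#' @param targets GRanges of capture targets (reference coordinates)
#' @param sampleVars this sample's variants (rows of the truth set), used
#'   only to transform the padded spans into haplotype coordinates
#' @param config a list from [simConfig()]
#' @param sample sample identifier used in read names
#' @return a data.frame with columns `readId`, `seqname`, `hapStart`,
#'   `strand`, `seq` (errors applied, reference orientation).
#' @export
sampleReads <- function(haplotype, targets, sampleVars,
                        config = simConfig(), sample = "sample1") {
    rl <- config$readLength
    rows <- list()
    counter <- 0L
    for (t in seq_along(targets)) {
        sn <- as.character(GenomicRanges::seqnames(targets))[t]
        vars <- sampleVars[sampleVars$seqname == sn, , drop = FALSE]
        hlen <- nchar(haplotype[[sn]])
        hs <- max(1L, .refToHap(GenomicRanges::start(targets)[t] - rl, vars))
        he <- min(hlen, .refToHap(GenomicRanges::end(targets)[t] + rl, vars))
        lastStart <- he - rl + 1L
        if (lastStart < hs) next
        nReads <- stats::rpois(1, config$meanDepth *
                                   (lastStart - hs + 1L) / rl)
        if (nReads == 0L) next
        starts <- hs - 1L + sample.int(lastStart - hs + 1L, nReads,
                                       replace = TRUE)
        strands <- ifelse(stats::rbinom(nReads, 1L, 0.5) == 1L, "-", "+")
        seqs <- substring(haplotype[[sn]], starts, starts + rl - 1L)
        if (config$errorRate > 0) {
            for (k in seq_len(nReads)) {
                errAt <- which(stats::runif(rl) < config$errorRate)
                for (e in errAt) {
                    old <- substr(seqs[k], e, e)
                    substr(seqs[k], e, e) <-
                        sample(setdiff(c("A", "C", "G", "T"), old), 1L)
                }
            }
        }
        rows[[t]] <- data.frame(
            readId = sprintf("%s_t%02d_r%05d", sample, t,
                             counter + seq_len(nReads)),
            seqname = sn, hapStart = starts, strand = strands, seq = seqs,
            stringsAsFactors = FALSE)
        counter <- counter + nReads
    }
    if (!length(rows))
        return(data.frame(readId = character(), seqname = character(),
                          hapStart = integer(), strand = character(),
                          seq = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Emulate an end-gapped mapper
#'
#' Places each read at its true reference coordinate (transforming
#' haplotype coordinates through the sample's planted indels).  A read
#' crossing an indel breakpoint is anchored by its longer ungapped side and
#' the bases beyond the breakpoint become a soft clip; reads whose clip
#' would exceed `maxClipFraction` of the read length are emitted unclipped
#' at the anchor-side placement (their far side turns into mismatches, as a
#' real mapper's rejected gap would).  NM is the true mismatch count over
#' the aligned span; MAPQ is 60.
#'
#' @param reads data.frame from [sampleReads()]
#' @param reference DNAStringSet
#' @param sampleVars this sample's variants (rows of the truth set)
#' @param config a list from [simConfig()]
#' @return a data.frame of alignment records with the
#'   [PartialAlignments-class] columns (reads that cannot be placed on the
#'   reference are dropped).
#' @export
emulateMapping <- function(reads, reference, sampleVars,
                           config = simConfig()) {
    rl <- config$readLength
    maxClip <- as.integer(floor(config$maxClipFraction * rl))
    lens <- referenceLengths(reference)
    out <- vector("list", nrow(reads))
    for (k in seq_len(nrow(reads))) {
        sn <- reads$seqname[k]
        vars <- sampleVars[sampleVars$seqname == sn &
                               sampleVars$type != "SNV", , drop = FALSE]
        hs <- reads$hapStart[k]
        he <- hs + rl - 1L
        ## locate a crossed indel (isolation guarantees at most one)
        cross <- NULL
        for (j in seq_len(nrow(vars))) {
            if (vars$type[j] == "DEL") {
                hB <- .refToHap(vars$pos[j] - 1L,
                                vars[seq_len(j - 1L), , drop = FALSE])
                if (hs <= hB && he >= hB + 1L)
                    cross <- list(type = "DEL", v = vars[j, ], hB = hB)
            } else {
                hI <- .refToHap(vars$pos[j],
                                vars[seq_len(j - 1L), , drop = FALSE])
                if (he >= hI + 1L && hs <= hI + vars$length[j])
                    cross <- list(type = "INS", v = vars[j, ], hI = hI)
            }
            if (!is.null(cross)) break
        }
        if (is.null(cross)) {
            pos <- .hapToRef(hs, vars)
            rec <- .placeRead(reads[k, ], sn, pos, 0L, 0L, rl, lens)
        } else if (cross$type == "DEL") {
            prefixLen <- cross$hB - hs + 1L
            suffixLen <- rl - prefixLen
            if (prefixLen >= suffixLen) {
                pos <- .hapToRef(hs, vars)
                clip <- suffixLen; leftClip <- 0L; alignedLen <- prefixLen
            } else {
                pos <- .hapToRef(cross$hB + 1L, vars)
                clip <- prefixLen; leftClip <- clip; alignedLen <- suffixLen
            }
            if (clip > maxClip) {
                ## mapper rejects the gap: full-length ungapped placement
                pos <- if (prefixLen >= suffixLen) .hapToRef(hs, vars) else
                    .hapToRef(cross$hB + 1L, vars) - prefixLen
                rec <- .placeRead(reads[k, ], sn, pos, 0L, 0L, rl, lens)
            } else {
                rec <- .placeRead(reads[k, ], sn, pos, leftClip,
                                  rl - leftClip - alignedLen, rl, lens)
            }
        } else {                              # insertion
            hI <- cross$hI; L <- cross$v$length
            leftLen <- max(0L, min(he, hI) - hs + 1L)
            rightLen <- max(0L, he - (hI + L))
            if (leftLen >= rightLen) {
                pos <- .hapToRef(hs, vars)
                clip <- rl - leftLen; leftClip <- 0L; alignedLen <- leftLen
            } else {
                pos <- .hapToRef(hI + L + 1L, vars)
                clip <- rl - rightLen; leftClip <- clip
                alignedLen <- rightLen
            }
            if (clip > maxClip) {
                pos <- if (leftLen >= rightLen) .hapToRef(hs, vars) else
                    .hapToRef(hI + L + 1L, vars) - (rl - rightLen)
                rec <- .placeRead(reads[k, ], sn, pos, 0L, 0L, rl, lens)
            } else {
                rec <- .placeRead(reads[k, ], sn, pos, leftClip,
                                  rl - leftClip - alignedLen, rl, lens)
            }
        }
        out[[k]] <- rec
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out))
        return(alnTable(PartialAlignments(data.frame(
            readId = character(), seqname = character(), start = integer(),
            end = integer(), strand = character(), seq = character(),
            leftClip = integer(), rightClip = integer(),
            mismatches = integer(), mapq = integer(), isUnique = logical(),
            hasIndelOps = logical()))))
    recs <- do.call(rbind, out)
    rownames(recs) <- NULL
    recs[order(recs$seqname, recs$start, recs$readId, method = "radix"), ,
         drop = FALSE]
}

## Build one alignment record; NULL when the placement leaves the reference.
.placeRead <- function(read, sn, pos, leftClip, rightClip, rl, lens) {
    alignedLen <- rl - leftClip - rightClip
    end <- pos + alignedLen - 1L
    if (pos < 1L || end > lens[[sn]] || alignedLen < 1L) return(NULL)
    data.frame(readId = read$readId, seqname = sn, start = pos, end = end,
               strand = read$strand, seq = read$seq,
               leftClip = leftClip, rightClip = rightClip,
               mismatches = NA_integer_, mapq = 60L, isUnique = TRUE,
               hasIndelOps = FALSE, stringsAsFactors = FALSE)
}

## Fill NM as the true mismatch count of the aligned span vs the reference.
.fillMismatches <- function(recs, reference) {
    if (nrow(recs) == 0L) return(recs)
    for (k in seq_len(nrow(recs))) {
        alen <- recs$end[k] - recs$start[k] + 1L
        rd <- substr(recs$seq[k], recs$leftClip[k] + 1L,
                     recs$leftClip[k] + alen)
        rf <- as.character(Biostrings::subseq(
            reference[[recs$seqname[k]]], recs$start[k], recs$end[k]))
        recs$mismatches[k] <- sum(utf8ToInt(rd) != utf8ToInt(rf))
    }
    recs
}

#' Write alignment records as a text SAM file
#'
#' @param recs alignment records ([emulateMapping()] output)
#' @param reference DNAStringSet (for the `@SQ` header lines)
#' @param file output path
#' @return invisibly, the path.
#' @export
writeSam <- function(recs, reference, file) {
    lens <- referenceLengths(reference)
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
    lines <- hdr
    if (nrow(recs)) {
        cigar <- paste0(
            ifelse(recs$leftClip > 0L, paste0(recs$leftClip, "S"), ""),
            recs$end - recs$start + 1L, "M",
            ifelse(recs$rightClip > 0L, paste0(recs$rightClip, "S"), ""))
        flag <- ifelse(recs$strand == "-", 16L, 0L)
        lines <- c(lines, paste(
            recs$readId, flag, recs$seqname, recs$start, recs$mapq, cigar,
            "*", 0L, 0L, recs$seq, strrep("I", nchar(recs$seq)),
            paste0("NM:i:", recs$mismatches), sep = "\t"))
    }
    con <- file(file, open = "wb")
    writeLines(lines, con)
    close(con)
    invisible(file)
}

#' Simulate a complete multi-sample dataset
#'
#' Reference + targets, planted variants, and per-sample emulated
#' alignments, fully reproducible from the seed.
#'
#' @param variants variant request table (see [plantVariants()])
#' @param config a list from [simConfig()]
#' @param seed integer seed (applied with [set.seed()]); NULL leaves the
#'   RNG state untouched
#' @return a list with `reference`, `targets`, `truth`, `config`, and
#'   `alignments` (named list of per-sample record data.frames).
#' @export
simulateDataset <- function(variants, config = simConfig(), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    ref <- simulateReference(config)
    truth <- plantVariants(ref$reference, ref$targets, variants, config)
    alignments <- list()
    for (s in seq_len(config$nSamples)) {
        sampleId <- sprintf("sample%02d", s)
        vars <- .variantsFor(truth, s)
        hap <- buildHaplotype(ref$reference, truth, s)
        reads <- sampleReads(hap, ref$targets, vars, config,
                             sample = sampleId)
        recs <- emulateMapping(reads, ref$reference, vars, config)
        recs <- .fillMismatches(recs, ref$reference)
        alignments[[sampleId]] <- recs
    }
    list(reference = ref$reference, targets = ref$targets, truth = truth,
         config = config, alignments = alignments)
}

#' Write a simulated dataset to disk
#'
#' Emits reference FASTA, targets BED, per-sample SAM, a truth TSV
#' (positions 0-based in the `pos_0based` column to match the BED
#' convention, 1-based in `pos_1based`), and the configuration as a
#' key-value file.
#'
#' @param dataset list from [simulateDataset()]
#' @param dir output directory (created if needed)
#' @return invisibly, the directory.
#' @export
writeDataset <- function(dataset, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(dataset$reference,
                                file.path(dir, "reference.fasta"))
    tg <- dataset$targets
    bed <- paste(as.character(GenomicRanges::seqnames(tg)),
                 GenomicRanges::start(tg) - 1L, GenomicRanges::end(tg),
                 S4Vectors::mcols(tg)$label, sep = "\t")
    con <- file(file.path(dir, "targets.bed"), open = "wb")
    writeLines(bed, con); close(con)
    tr <- dataset$truth
    con <- file(file.path(dir, "truth.tsv"), open = "wb")
    writeLines(c(paste("seqname", "pos_0based", "pos_1based", "type",
                       "length", "seq", "samples", sep = "\t"),
                 paste(tr$seqname, tr$pos - 1L, tr$pos, tr$type, tr$length,
                       tr$seq, tr$samples, sep = "\t")), con)
    close(con)
    for (s in names(dataset$alignments))
        writeSam(dataset$alignments[[s]], dataset$reference,
                 file.path(dir, paste0(s, ".sam")))
    cfg <- dataset$config
    con <- file(file.path(dir, "config.txt"), open = "wb")
    writeLines(sprintf("%s=%s", names(cfg),
                       vapply(cfg, function(v) paste(v, collapse = ","),
                              character(1))), con)
    close(con)
    invisible(dir)
}

#' Score recovery of planted indels
#'
#' A truth indel is recovered iff a PASS candidate of the same type lies
#' within `tolerance` positions (candidate `variantStart` vs truth `pos`).
#' False positives are PASS resolved candidates matching no truth indel.
#'
#' @param candidates a PASS candidate data.frame ([passCandidates()])
#' @param truth truth set from [plantVariants()]
#' @param tolerance maximum position error (default 1)
#' @return a list with `table` (per truth indel: `detected`, `posError`,
#'   `typeMatch`, `lengthMatch`, `seqMatch`), `nRecovered`, and
#'   `falsePositives`.
#' @export
scoreRecovery <- function(candidates, truth, tolerance = 1L) {
    ti <- truth[truth$type %in% c("INS", "DEL"), , drop = FALSE]
    cand <- candidates[candidates$callType %in%
                           c("deletion", "insertion"), , drop = FALSE]
    typeOf <- c(deletion = "DEL", insertion = "INS")
    matchedCand <- rep(FALSE, nrow(cand))
    n <- nrow(ti)
    det <- logical(n); posErr <- rep(NA_integer_, n)
    lenM <- logical(n); seqM <- logical(n)
    for (i in seq_len(n)) {
        hit <- which(cand$seqname == ti$seqname[i] &
                         typeOf[cand$callType] == ti$type[i] &
                         abs(cand$variantStart - ti$pos[i]) <= tolerance)
        if (length(hit)) {
            best <- hit[which.min(abs(cand$variantStart[hit] - ti$pos[i]))]
            det[i] <- TRUE
            posErr[i] <- abs(cand$variantStart[best] - ti$pos[i])
            lenM[i] <- cand$callLength[best] == ti$length[i]
            seqM[i] <- cand$callSeq[best] == ti$seq[i]
            matchedCand[hit] <- TRUE
        }
    }
    ## any-type proximity counts against false-positive status
    for (j in seq_len(nrow(cand))) {
        if (!matchedCand[j] && nrow(ti) &&
            any(cand$seqname[j] == ti$seqname &
                    abs(cand$variantStart[j] - ti$pos) <= tolerance))
            matchedCand[j] <- TRUE
    }
    list(table = data.frame(ti, detected = det, posError = posErr,
                            typeMatch = det, lengthMatch = lenM,
                            seqMatch = seqM, stringsAsFactors = FALSE),
         nRecovered = sum(det),
         falsePositives = sum(!matchedCand))
}
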