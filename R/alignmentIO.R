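## Format boundary: FASTA / SAM / BED / VCF in, TSV + minimal VCF out.
## Internal coordinates are 1-based inclusive throughout; BED (0-based
## half-open) and SAM/VCF (1-based) are converted at the boundary.

#' Read a reference FASTA
#'
#' Loads all records, uppercases, and maps any character outside A/C/G/T/N
#' to N.  Duplicate record names and empty files are errors.
#'
#' @param file path to a FASTA file
#' @return a [Biostrings::DNAStringSet], one element per reference sequence.
#' @export
readReference <- function(file) {
    x <- Biostrings::readBStringSet(file)
    if (length(x) == 0L)
        stop("no sequences in FASTA file: ", file)
    nm <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(nm))
        stop("duplicate sequence names in FASTA: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    s <- toupper(as.character(x))
    s <- gsub("[^ACGTN]", "N", s)
    out <- Biostrings::DNAStringSet(s)
    names(out) <- nm
    if (any(Biostrings::width(out) == 0L))
        stop("empty sequence in FASTA: ", file)
    out
}

#' Reference sequence lengths
#'
#' @param reference a DNAStringSet as returned by [readReference()]
#' @return named integer vector of sequence lengths.
#' @export
referenceLengths <- function(reference) {
    stats::setNames(Biostrings::width(reference), names(reference))
}

.parseCigar <- function(cigar) {
    ops <- GenomicAlignments::explodeCigarOps(cigar)
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
    n <- length(cigar)
    leftClip <- integer(n); rightClip <- integer(n)
    refWidth <- integer(n); hasIndel <- logical(n)
    for (i in seq_len(n)) {
        o <- ops[[i]]; l <- lens[[i]]
        keep <- o != "H"           # hard-clipped bases are not in SEQ
        o <- o[keep]; l <- l[keep]
        if (length(o) && o[1] == "S") leftClip[i] <- l[1]
        if (length(o) > 1L && o[length(o)] == "S") rightClip[i] <- l[length(o)]
        refWidth[i] <- sum(l[o %in% c("M", "D", "N", "=", "X")])
        hasIndel[i] <- any(o %in% c("I", "D", "N"))
    }
    list(leftClip = leftClip, rightClip = rightClip,
         refWidth = refWidth, hasIndelOps = hasIndel)
}

#' Read single-end alignments from SAM/BAM into the partial-alignment model
#'
#' Soft clips at either read end are the "partially mapped" evidence this
#' package consumes.  Secondary, supplementary and unmapped records are
#' skipped.  Mismatch counts come from the NM tag when present, otherwise
#' they are recomputed against the reference over the aligned span.
#'
#' @param file path to a SAM (text) or BAM file with `@SQ` headers
#' @param reference optional DNAStringSet; when supplied, sequence names are
#'   validated against it and missing NM tags are recomputed.
#' @param uniqueMapqThreshold minimum MAPQ for an alignment to count as
#'   uniquely mapped (default 1).
#' @return a [PartialAlignments-class] object.
#' @export
readAlignments <- function(file, reference = NULL, uniqueMapqThreshold = 1L) {
    bam <- file
    if (grepl("\\.sam$", file, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        bam <- Rsamtools::asBam(file, dest, overwrite = TRUE,
                                indexDestination = FALSE)
    }
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "strand", "pos", "mapq",
                 "cigar", "seq"),
        tag = "NM",
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE,
                                      isSupplementaryAlignment = FALSE))
    x <- Rsamtools::scanBam(bam, param = param)[[1]]
    n <- length(x$qname)
    empty <- PartialAlignments(data.frame(
        readId = character(), seqname = character(), start = integer(),
        end = integer(), strand = character(), seq = character(),
        leftClip = integer(), rightClip = integer(), mismatches = integer(),
        mapq = integer(), isUnique = logical(), hasIndelOps = logical()))
    if (n == 0L) return(empty)

    seqname <- as.character(x$rname)
    if (!is.null(reference)) {
        bad <- setdiff(unique(seqname), names(reference))
        if (length(bad))
            stop("alignment sequence(s) absent from reference: ",
                 paste(bad, collapse = ", "))
    }
    cig <- .parseCigar(x$cigar)
    seq <- as.character(x$seq)
    qname <- x$qname; strand <- as.character(x$strand)
    pos <- x$pos; mapq <- x$mapq
    nm <- x$tag$NM
    if (is.null(nm)) nm <- rep(NA_integer_, n)
    noSeq <- is.na(seq) | seq == "" | seq == "*"
    if (any(noSeq)) {
        clipped <- noSeq & (cig$leftClip > 0L | cig$rightClip > 0L)
        if (any(clipped))
            warning(sum(clipped),
                    " clipped record(s) without stored sequence skipped")
        keep <- !noSeq
        qname <- qname[keep]; strand <- strand[keep]
        pos <- pos[keep]; mapq <- mapq[keep]; nm <- nm[keep]
        seqname <- seqname[keep]; seq <- seq[keep]
        cig <- lapply(cig, `[`, keep)
        n <- sum(keep)
        if (n == 0L) return(empty)
    }
    start <- pos
    end <- start + cig$refWidth - 1L
    needNM <- is.na(nm)
    if (any(needNM)) {
        if (is.null(reference))
            nm[needNM] <- 0L
        else {
            for (i in which(needNM)) {
                if (cig$hasIndelOps[i]) { nm[i] <- 0L; next }
                alen <- end[i] - start[i] + 1L
                rd <- substr(seq[i], cig$leftClip[i] + 1L,
                             cig$leftClip[i] + alen)
                rf <- as.character(Biostrings::subseq(
                    reference[[seqname[i]]], start[i], end[i]))
                nm[i] <- sum(utf8ToInt(rd) != utf8ToInt(rf))
            }
        }
    }
    PartialAlignments(data.frame(
        readId = qname,
        seqname = seqname,
        start = start,
        end = end,
        strand = strand,
        seq = seq,
        leftClip = cig$leftClip,
        rightClip = cig$rightClip,
        mismatches = as.integer(nm),
        mapq = mapq,
        isUnique = !is.na(mapq) & mapq >= uniqueMapqThreshold,
        hasIndelOps = cig$hasIndelOps,
        stringsAsFactors = FALSE))
}

#' Read capture-target intervals from BED
#'
#' BED is 0-based half-open; the returned GRanges is 1-based inclusive.
#' Empty intervals (start >= end) are rejected.  Overlapping intervals are
#' preserved as given (no merging).
#'
#' @param file path to a BED file (3+ columns)
#' @param reference optional DNAStringSet for bounds validation
#' @return a [GenomicRanges::GRanges] of target regions; the BED name column
#'   (when present) is kept as `label`.
#' @export
readTargets <- function(file, reference = NULL) {
    gr <- rtracklayer::import(file, format = "BED")
    if (any(IRanges::width(gr) < 1L))
        stop("empty target interval(s) (start >= end) in ", file)
    if (!is.null(reference)) {
        lens <- referenceLengths(reference)
        sn <- as.character(GenomicRanges::seqnames(gr))
        bad <- !(sn %in% names(lens)) |
            GenomicRanges::start(gr) < 1L |
            GenomicRanges::end(gr) > lens[sn]
        if (any(bad))
            stop(sum(bad), " target interval(s) outside reference bounds")
    }
    lbl <- S4Vectors::mcols(gr)$name
    if (is.null(lbl)) lbl <- paste0("target", seq_along(gr))
    S4Vectors::mcols(gr)$label <- lbl
    gr
}

#' Read known polymorphic positions from VCF or BED
#'
#' VCF records spanning more than one reference base contribute every
#' covered position; BED intervals contribute every base of the interval.
#' Positions are returned 1-based.
#'
#' @param file path to a `.vcf` or `.bed` file (dialect chosen by extension)
#' @param reference optional DNAStringSet for bounds validation
#' @return a width-1 [GenomicRanges::GRanges], one range per known position
#'   (deduplicated, sorted).
#' @export
readKnownVariants <- function(file, reference = NULL) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "vcf") {
        v <- VariantAnnotation::readVcf(file, genome = "unknown")
        gr <- SummarizedExperiment::rowRanges(v)
    } else if (ext == "bed") {
        gr <- rtracklayer::import(file, format = "BED")
    } else {
        stop("unknown known-variants format (expect .vcf or .bed): ", file)
    }
    if (length(gr) == 0L)
        return(GenomicRanges::GRanges())
    pos <- GenomicRanges::GRanges(
        rep(as.character(GenomicRanges::seqnames(gr)),
            IRanges::width(gr)),
        IRanges::IRanges(start = unlist(Map(
            seq.int, GenomicRanges::start(gr), GenomicRanges::end(gr))),
            width = 1L))
    pos <- sort(unique(pos))
    if (!is.null(reference)) {
        lens <- referenceLengths(reference)
        sn <- as.character(GenomicRanges::seqnames(pos))
        bad <- !(sn %in% names(lens)) |
            GenomicRanges::start(pos) < 1L |
            GenomicRanges::start(pos) > lens[sn]
        if (any(bad))
            stop(sum(bad), " known-variant position(s) outside reference")
    }
    pos
}

.fmtNum <- function(x) {
    ifelse(is.na(x), "NA", trimws(formatC(x, digits = 6, format = "g")))
}

#' Write indel candidates as a TSV report and a minimal VCF
#'
#' Positions are reported 1-based.  Output is byte-identical across reruns
#' on identical input (fixed ordering and number formatting).
#'
#' @param x an [IndelCandidates-class] object
#' @param tsv path for the tab-delimited report (all candidates, including
#'   filtered ones, with their failed-filter annotations)
#' @param vcf optional path for a minimal VCF of resolved candidates;
#'   requires `reference` for REF/ALT alleles
#' @param reference DNAStringSet (required when `vcf` is given)
#' @return invisibly, the TSV path.
#' @export
writeCandidates <- function(x, tsv, vcf = NULL, reference = NULL) {
    d <- candidateTable(x)
    ord <- order(d$sample, d$seqname, d$p, d$direction, method = "radix")
    d <- d[ord, , drop = FALSE]
    rep <- data.frame(
        sample = d$sample, seq = d$seqname, pos_1based = d$p,
        direction = d$direction, N_p = d$Np, N_pm1 = d$Npm1,
        N_both = d$Nboth, r = .fmtNum(d$r), support = d$support,
        gap_consensus = d$consensus, call_type = d$callType,
        call_length = ifelse(d$callType == "unresolved", ".",
                             as.character(d$callLength)),
        call_sequence = ifelse(d$callType == "unresolved", ".", d$callSeq),
        filters_failed = ifelse(d$filtersFailed == "", "PASS",
                                d$filtersFailed),
        stringsAsFactors = FALSE)
    con <- file(tsv, open = "wb")
    writeLines(paste(colnames(rep), collapse = "\t"), con)
    if (nrow(rep))
        writeLines(do.call(paste, c(unname(rep), sep = "\t")), con)
    close(con)

    if (!is.null(vcf)) {
        if (is.null(reference))
            stop("writing VCF output requires the reference")
        res <- d[d$callType != "unresolved", , drop = FALSE]
        lines <- c("##fileformat=VCFv4.2",
                   "##source=ClipIndel",
                   paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT",
                                       "QUAL", "FILTER", "INFO"),
                                     collapse = "\t")))
        for (i in seq_len(nrow(res))) {
            sn <- res$seqname[i]
            if (res$callType[i] == "deletion") {
                pos <- res$variantStart[i] - 1L
                anchor <- as.character(Biostrings::subseq(
                    reference[[sn]], pos, pos))
                ref <- paste0(anchor, res$callSeq[i]); alt <- anchor
            } else {
                pos <- res$variantStart[i]
                anchor <- as.character(Biostrings::subseq(
                    reference[[sn]], pos, pos))
                ref <- anchor; alt <- paste0(anchor, res$callSeq[i])
            }
            filt <- if (res$filtersFailed[i] == "") "PASS" else
                gsub(",", ";", res$filtersFailed[i])
            info <- sprintf("SAMPLE=%s;R=%s;SUPPORT=%d;TYPE=%s;LEN=%d",
                            res$sample[i], .fmtNum(res$r[i]),
                            res$support[i],
                            toupper(substr(res$callType[i], 1, 3)),
                            res$callLength[i])
            lines <- c(lines, paste(sn, pos, ".", ref, alt, ".", filt, info,
                                    sep = "\t"))
        }
        con <- file(vcf, open = "wb")
        writeLines(lines, con)
        close(con)
    }
    invisible(tsv)
}

#' Write single-base candidates as a TSV report and a minimal VCF
#'
#' @param snvs a data.frame of single-base candidates (columns `sample`,
#'   `seqname`, `pos`, `ref`, `alt`, `depth`, `altCount`, `fraction`, and
#'   optionally `consequence`)
#' @param tsv path for the tab-delimited report
#' @param vcf optional path for a minimal VCF
#' @return invisibly, the TSV path.
#' @export
writeSnvCandidates <- function(snvs, tsv, vcf = NULL) {
    d <- snvs
    if (is.null(d$consequence)) d$consequence <- "unknown"
    ord <- order(d$sample, d$seqname, d$pos, method = "radix")
    d <- d[ord, , drop = FALSE]
    rep <- data.frame(
        sample = d$sample, seq = d$seqname, pos_1based = d$pos,
        ref = d$ref, alt = d$alt, depth = d$depth, alt_count = d$altCount,
        fraction = .fmtNum(d$fraction), consequence = d$consequence,
        stringsAsFactors = FALSE)
    con <- file(tsv, open = "wb")
    writeLines(paste(colnames(rep), collapse = "\t"), con)
    if (nrow(rep))
        writeLines(do.call(paste, c(unname(rep), sep = "\t")), con)
    close(con)
    if (!is.null(vcf)) {
        lines <- c("##fileformat=VCFv4.2",
                   "##source=ClipIndel",
                   paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT",
                                       "QUAL", "FILTER", "INFO"),
                                     collapse = "\t")))
        if (nrow(d))
            lines <- c(lines, paste(
                d$seqname, d$pos, ".", d$ref, d$alt, ".", "PASS",
                sprintf("SAMPLE=%s;DP=%d;AF=%s;CSQ=%s", d$sample, d$depth,
                        .fmtNum(d$fraction), d$consequence),
                sep = "\t"))
        con <- file(vcf, open = "wb")
        writeLines(lines, con)
        close(con)
    }
    invisible(tsv)
}
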