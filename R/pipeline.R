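## Workflow wiring: the indel workflow (mapping filters -> clip events ->
## breakpoint statistic -> tail consensus -> classification -> filter
## stack -> cross-sample recurrence), the single-base workflow, and
## target-coverage statistics.  These functions back the command-line
## interface in inst/scripts/clipindel.R.

.loadReference <- function(reference) {
    if (is.character(reference)) readReference(reference) else reference
}

.loadTargets <- function(targets, reference) {
    if (is.null(targets)) return(NULL)
    if (is.character(targets)) readTargets(targets, reference) else targets
}

.loadKnown <- function(known, reference) {
    if (is.null(known)) return(NULL)
    if (is.character(known)) readKnownVariants(known, reference) else known
}

#' Run the clipped-read indel workflow over one or more samples
#'
#' For each sample: parse alignments, apply the mapping filters, collect
#' clip events, evaluate the breakpoint statistic and tail consensus,
#' classify candidates, and annotate them with the filter stack.  Across
#' samples, candidates recurring at one position in more than
#' `config@maxSamplesIndel` samples are flagged `"recurrent"`.
#'
#' @param samFiles named character vector of SAM/BAM paths (names = sample
#'   ids; unnamed vectors get `sample1`, `sample2`, ...)
#' @param reference DNAStringSet or FASTA path
#' @param targets GRanges, BED path, or NULL
#' @param known width-1 GRanges, VCF/BED path, or NULL
#' @param config a [FilterConfig-class]
#' @param uniqueMapqThreshold,maxMismatches,maxClipFraction mapping filters
#' @param countMapperIndels see [collectClipEvents()]
#' @param outDir if non-NULL, per-sample TSV/VCF reports and a JSON manifest
#'   are written there
#' @return a list with `candidates` (named list of
#'   [IndelCandidates-class], filter-annotated) and `manifest` (per-stage
#'   record counts per sample).
#' @export
runParMap <- function(samFiles, reference, targets = NULL, known = NULL,
                      config = filterConfig(), uniqueMapqThreshold = 1L,
                      maxMismatches = 2L, maxClipFraction = 0.2,
                      countMapperIndels = FALSE, outDir = NULL) {
    stopifnot(length(samFiles) >= 1L)
    samples <- names(samFiles)
    if (is.null(samples))
        samples <- paste0("sample", seq_along(samFiles))
    reference <- .loadReference(reference)
    targets <- .loadTargets(targets, reference)
    known <- .loadKnown(known, reference)

    manifest <- list(version = as.character(utils::packageVersion("ClipIndel")),
                     config = list(rThreshold = config@rThreshold,
                                   minReads = config@minReads,
                                   boundaryWindow = config@boundaryWindow,
                                   maxSamplesIndel = config@maxSamplesIndel,
                                   maxMismatches = maxMismatches,
                                   maxClipFraction = maxClipFraction),
                     samples = list())
    tables <- list()
    for (i in seq_along(samFiles)) {
        pa <- readAlignments(samFiles[[i]], reference,
                             uniqueMapqThreshold = uniqueMapqThreshold)
        nParsed <- length(pa)
        pa <- filterAlignments(pa, maxMismatches = maxMismatches,
                               maxClipFraction = maxClipFraction)
        nPass <- length(pa)
        cand <- callCandidates(pa, reference, targets, sample = samples[i],
                               countMapperIndels = countMapperIndels)
        cand <- applyFilters(cand, config, known = known, targets = targets)
        tables[[samples[i]]] <- candidateTable(cand)
        manifest$samples[[samples[i]]] <- list(
            readsParsed = nParsed, readsPassingFilters = nPass,
            candidatesEvaluated = length(cand))
    }
    tables <- crossSampleFilter(tables, maxSamples = config@maxSamplesIndel,
                                posColumn = "variantStart", annotate = TRUE)
    candidates <- lapply(tables, IndelCandidates)
    for (s in samples) {
        d <- tables[[s]]
        manifest$samples[[s]]$candidatesPass <- sum(d$filtersFailed == "")
        manifest$samples[[s]]$candidatesFailingFilters <-
            sum(d$filtersFailed != "")
    }
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        for (s in samples)
            writeCandidates(candidates[[s]],
                            tsv = file.path(outDir,
                                            paste0(s, ".indels.tsv")),
                            vcf = file.path(outDir,
                                            paste0(s, ".indels.vcf")),
                            reference = reference)
        jsonlite::write_json(manifest,
                             file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE)
    }
    list(candidates = candidates, manifest = manifest)
}

#' Run the single-base variant workflow over one or more samples
#'
#' @inheritParams runParMap
#' @param cds CDS annotation data.frame ([readCdsAnnotation()]), TSV path,
#'   or NULL
#' @param minDepth,minFraction see [callSnvs()]
#' @param nonsynonymousOnly restrict output to non-synonymous candidates
#' @return a list with `snvs` (named list of per-sample candidate
#'   data.frames) and `manifest`.
#' @export
runSnv <- function(samFiles, reference, cds = NULL, known = NULL,
                   config = filterConfig(), minDepth = 3L,
                   minFraction = 0.75, nonsynonymousOnly = FALSE,
                   uniqueMapqThreshold = 1L, maxMismatches = 2L,
                   maxClipFraction = 0.2, outDir = NULL) {
    stopifnot(length(samFiles) >= 1L)
    samples <- names(samFiles)
    if (is.null(samples))
        samples <- paste0("sample", seq_along(samFiles))
    reference <- .loadReference(reference)
    known <- .loadKnown(known, reference)
    if (is.character(cds)) cds <- readCdsAnnotation(cds, reference)
    if (nonsynonymousOnly && is.null(cds))
        stop("--nonsynonymous-only requires a CDS annotation")
    alns <- list()
    manifest <- list(version = as.character(utils::packageVersion("ClipIndel")),
                     samples = list())
    for (i in seq_along(samFiles)) {
        pa <- readAlignments(samFiles[[i]], reference,
                             uniqueMapqThreshold = uniqueMapqThreshold)
        nParsed <- length(pa)
        pa <- filterAlignments(pa, maxMismatches = maxMismatches,
                               maxClipFraction = maxClipFraction)
        alns[[samples[i]]] <- pa
        manifest$samples[[samples[i]]] <- list(
            readsParsed = nParsed, readsPassingFilters = length(pa))
    }
    snvs <- snvPipeline(alns, reference, cds = cds, known = known,
                        minDepth = minDepth, minFraction = minFraction,
                        maxSamples = config@maxSamplesSnv,
                        nonsynonymousOnly = nonsynonymousOnly)
    for (s in samples)
        manifest$samples[[s]]$candidates <- nrow(snvs[[s]])
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        for (s in samples)
            writeSnvCandidates(snvs[[s]],
                               tsv = file.path(outDir,
                                               paste0(s, ".snvs.tsv")),
                               vcf = file.path(outDir,
                                               paste0(s, ".snvs.vcf")))
        jsonlite::write_json(manifest,
                             file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE)
    }
    list(snvs = snvs, manifest = manifest)
}

#' Target coverage statistics
#'
#' Breadth = fraction of target bases covered by at least one aligned base;
#' depth = mean aligned depth over all target bases (zeros included).
#' Clipped bases do not count as coverage.
#'
#' @param samFile SAM/BAM path (or a [PartialAlignments-class] object)
#' @param targets GRanges or BED path
#' @param reference DNAStringSet or FASTA path (optional, for validation)
#' @return a list with `breadth`, `meanDepth`, `targetBases`,
#'   `coveredBases`.
#' @export
runStats <- function(samFile, targets, reference = NULL) {
    if (!is.null(reference)) reference <- .loadReference(reference)
    targets <- .loadTargets(targets, reference)
    pa <- if (is(samFile, "PartialAlignments")) samFile else
        readAlignments(samFile, reference)
    totalBases <- sum(IRanges::width(targets))
    if (length(pa) == 0L)
        return(list(breadth = 0, meanDepth = 0, targetBases = totalBases,
                    coveredBases = 0L))
    cov <- GenomicRanges::coverage(alignedRanges(pa))
    covered <- 0L
    depthSum <- 0
    sn <- as.character(GenomicRanges::seqnames(targets))
    for (t in seq_along(targets)) {
        if (!(sn[t] %in% names(cov))) next
        rl <- cov[[sn[t]]]
        lo <- GenomicRanges::start(targets)[t]
        hi <- min(GenomicRanges::end(targets)[t], length(rl))
        if (hi < lo) next
        seg <- as.integer(S4Vectors::window(rl, lo, hi))
        covered <- covered + sum(seg > 0L)
        depthSum <- depthSum + sum(seg)
    }
    list(breadth = covered / totalBases,
         meanDepth = depthSum / totalBases,
         targetBases = totalBases, coveredBases = covered)
}
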