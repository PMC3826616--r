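#' @include shift-estimation.R
NULL

#' Default pipeline parameters
#'
#' The standard parameter set: preliminary shift-estimation pass with
#' bandwidth 50 nt, fold-enrichment threshold 25x, kurtosis threshold 50,
#' minimum strand correlation 0.3, shift grid 25-150 nt with vote-curve
#' bandwidth 5 nt; final calling with bandwidth 100 nt (to capture
#' binding sites in close proximity), the same fold/kurtosis/correlation
#' thresholds, and a 500 bp maximum region size.
#'
#' @return A named list of parameters.
#' @export
unipeakDefaults <- function() {
    list(bandwidth = 100L, prelimBandwidth = 50L,
         foldThreshold = 25, prelimFoldThreshold = 25,
         kurtosisMax = 50, rawKurtosis = FALSE,
         minStrandCorr = 0.3, maxRegionLength = 500L,
         minShift = 25L, maxShift = 150L, curveBw = 5,
         topShiftRegions = 1000L)
}

#' Read a YAML pipeline configuration
#'
#' Keys mirror \code{\link{unipeakDefaults}}; unknown keys are an error,
#' missing keys take the defaults.
#'
#' @param path YAML file.
#' @return A full parameter list.
#' @export
readUniPeakConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    defs <- unipeakDefaults()
    unknown <- setdiff(names(cfg), names(defs))
    if (length(unknown) > 0L)
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    utils::modifyList(defs, cfg)
}

## Pooled shifted strand density across the calling samples: each
## sample's forward profile translated by +s_i, reverse by -s_i.
.pooledShiftedStrand <- function(profiles, shifts, sign) {
    vals <- NULL
    for (i in seq_along(profiles)) {
        s <- sign * shifts[i]
        shifted <- lapply(profiles[[i]]@values, .shiftRle, s = s)
        shifted <- as(shifted, "RleList")
        names(shifted) <- names(profiles[[i]]@values)
        vals <- if (is.null(vals)) shifted else vals + shifted
    }
    vals
}

#' Run the full multi-sample peak-calling pipeline
#'
#' Orchestrates, for a set of hit tracks sharing one genome layout:
#' per-sample strand-shift estimation from preliminary regions (ChIP
#' samples only; controls and histone marks receive the median ChIP
#' shift), kernel smoothing of each strand at the final bandwidth,
#' strand-shifted unification per sample, pooling across ChIP samples,
#' enriched-region calling against the uniform background, kurtosis and
#' strand-correlation artifact filters, structural filters (excluded
#' chromosomes, blacklist, maximum size), and per-sample hit counting
#' within the surviving regions for every sample including controls.
#'
#' @param tracks list of \linkS4class{HitTrack} objects; at least one
#'   must be a non-control, non-histone ChIP sample.
#' @param layout the \linkS4class{GenomeLayout}.
#' @param params parameter list as from \code{\link{unipeakDefaults}};
#'   individual entries can be overridden via \code{...}.
#' @param ... named parameter overrides.
#' @return A \link[SummarizedExperiment]{RangedSummarizedExperiment} with
#'   the \code{counts} assay; \code{metadata()} carries the per-sample
#'   shifts, the parameters, and a filter tally.
#' @export
runUniPeak <- function(tracks, layout, params = unipeakDefaults(), ...) {
    over <- list(...)
    if (length(over) > 0L) params <- utils::modifyList(params, over)
    info <- lapply(tracks, sampleInfo)
    ids <- vapply(info, function(s) s@sampleId, "")
    if (anyDuplicated(ids)) stop("duplicate sample ids")
    names(tracks) <- ids
    isCalling <- !vapply(info, function(s) s@isControl || s@isHistone,
                         TRUE)
    if (!any(isCalling))
        stop("no ChIP (non-control, non-histone) samples to call regions",
             " from")

    ## per-sample shift, ChIP samples only
    shifts <- integer(length(tracks)); names(shifts) <- ids
    estimates <- list()
    for (id in ids[isCalling]) {
        est <- estimateSampleShift(tracks[[id]], layout,
            h = params$prelimBandwidth,
            foldThreshold = params$prelimFoldThreshold,
            kurtosisMax = params$kurtosisMax,
            topN = params$topShiftRegions,
            minShift = params$minShift, maxShift = params$maxShift,
            curveBw = params$curveBw, minCorr = params$minStrandCorr)
        shifts[id] <- strandShift(est)
        estimates[[id]] <- est
    }
    if (any(!isCalling))
        shifts[ids[!isCalling]] <- assignControlShift(shifts[isCalling])

    ## unified per-sample profiles at the final bandwidth, then pooled
    fwdProfiles <- lapply(tracks[isCalling], smoothProfile,
                          h = params$bandwidth, useStrand = "+")
    revProfiles <- lapply(tracks[isCalling], smoothProfile,
                          h = params$bandwidth, useStrand = "-")
    unified <- mapply(combineProfiles, fwdProfiles, revProfiles,
                      shifts[isCalling], SIMPLIFY = FALSE)
    pooled <- pooledProfile(unified)
    totalReads <- sum(vapply(tracks[isCalling], totalHits, numeric(1)))

    regions <- callRegions(pooled, totalReads, layout,
                           params$foldThreshold)
    nRaw <- length(regions)

    ## pooled shifted 5' starts for the kurtosis filter
    shiftedStarts <- GRanges()
    for (id in ids[isCalling]) {
        g <- hits(shiftTrack(tracks[[id]], shifts[id]))
        shiftedStarts <- c(shiftedStarts,
                           GRanges(seqnames(g),
                                   IRanges(start(g), width = 1L),
                                   score = mcols(g)$score))
    }
    regions <- .annotateKurtosis(regions, shiftedStarts,
                                 params$kurtosisMax,
                                 raw = params$rawKurtosis)
    fwdPooled <- .pooledShiftedStrand(fwdProfiles, shifts[isCalling], 1L)
    revPooled <- .pooledShiftedStrand(revProfiles, shifts[isCalling], -1L)
    regions <- annotateStrandCorrelation(regions, fwdPooled, revPooled,
                                         params$minStrandCorr)
    keep <- mcols(regions)$kurtosisPass & mcols(regions)$strandCorrPass
    nKurtosisFail <- sum(!mcols(regions)$kurtosisPass)
    nStrandFail <- sum(!mcols(regions)$strandCorrPass)
    regions <- regions[keep]
    nBeforeStructural <- length(regions)
    regions <- applyStructuralFilters(regions, layout,
                                      params$maxRegionLength)
    nStructuralDropped <- nBeforeStructural - length(regions)

    se <- countHits(regions, tracks, shifts)
    metadata(se)$shifts <- shifts
    metadata(se)$shiftEstimates <- estimates
    metadata(se)$params <- params
    metadata(se)$filterTally <- list(
        rawRegions = nRaw, kurtosisFailed = nKurtosisFail,
        strandCorrFailed = nStrandFail,
        structuralDropped = nStructuralDropped,
        finalRegions = length(regions))
    metadata(se)$totalReads <- totalReads
    se
}

#' Export called regions as BED6
#'
#' Name is the region id; the score column is the pooled peak height
#' scaled linearly to [0, 1000] over the region set.
#'
#' @param se result of \code{\link{runUniPeak}} (or a regions
#'   \code{GRanges} with \code{peakHeight}).
#' @param path output file.
#' @return Invisibly, the path.
#' @export
exportRegionsBed <- function(se, path) {
    gr <- if (is(se, "SummarizedExperiment")) rowRanges(se) else se
    hmax <- if (length(gr)) max(mcols(gr)$peakHeight) else 1
    sc <- if (hmax > 0) as.integer(round(1000 * mcols(gr)$peakHeight /
                                         hmax)) else 0L
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     name = if (!is.null(names(gr))) names(gr) else
                         sprintf("region_%05d", seq_along(gr)),
                     score = sc, strand = ".")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Write the count (or occupancy) matrix as TSV with metadata header
#'
#' Sample metadata rows (\code{#field} lines) precede the matrix so the
#' file is self-describing.
#'
#' @param se a \code{SummarizedExperiment} from \code{\link{runUniPeak}}
#'   or \code{\link{normalizeOccupancy}}.
#' @param path output file.
#' @param assayName which assay to write (default: first).
#' @return Invisibly, the path.
#' @export
writeCountMatrix <- function(se, path, assayName = NULL) {
    mat <- if (is.null(assayName)) assay(se, 1) else assay(se, assayName)
    cd <- colData(se)
    con <- file(path, "w")
    on.exit(close(con))
    for (f in colnames(cd))
        writeLines(paste(c(paste0("#", f), as.character(cd[[f]])),
                         collapse = "\t"), con)
    writeLines(paste(c("region", colnames(mat)), collapse = "\t"), con)
    rn <- if (!is.null(rownames(mat))) rownames(mat) else
        sprintf("region_%05d", seq_len(nrow(mat)))
    body <- apply(mat, 1L, function(r)
        paste(format(r, trim = TRUE, scientific = FALSE), collapse = "\t"))
    if (nrow(mat) > 0L) writeLines(paste(rn, body, sep = "\t"), con)
    invisible(path)
}

#' Write the pipeline QC report as JSON
#'
#' Per-sample shifts, the parameters used, and the filter tally.
#'
#' @param se result of \code{\link{runUniPeak}}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeQcJson <- function(se, path) {
    qc <- list(shifts = as.list(metadata(se)$shifts),
               params = metadata(se)$params,
               totalReads = metadata(se)$totalReads,
               filterTally = metadata(se)$filterTally)
    writeLines(jsonlite::toJSON(qc, auto_unbox = TRUE, digits = 10,
                                pretty = TRUE), path)
    invisible(path)
}
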