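#' @include region-calling.R
NULL

#' Preliminary enriched regions for shift estimation
#'
#' Calls strong candidate regions from one sample's own unshifted
#' both-strand profile: the two strand profiles are smoothed (bandwidth
#' 50 nt by default), summed without shifting, thresholded at the
#' fold-enrichment cutoff against the sample's uniform background,
#' kurtosis-filtered, ranked by contained read count and truncated to the
#' strongest \code{topN} (1000 by default).
#'
#' @param track a \linkS4class{HitTrack}.
#' @param layout a \linkS4class{GenomeLayout}.
#' @param h preliminary smoothing bandwidth (bp, default 50).
#' @param foldThreshold fold-enrichment threshold (default 25).
#' @param kurtosisMax kurtosis filter threshold (default 50).
#' @param topN number of top regions retained (default 1000).
#' @return A list with the region \code{GRanges} (ranked by hit count,
#'   descending) and the \code{fwd}/\code{rev} strand profiles used.
#' @export
preliminaryRegions <- function(track, layout, h = 50, foldThreshold = 25,
                               kurtosisMax = 50, topN = 1000) {
    fwd <- smoothProfile(track, h, "+")
    rev <- smoothProfile(track, h, "-")
    pooled <- combineProfiles(fwd, rev, 0L)
    regions <- callRegions(pooled, totalHits(track), layout,
                           foldThreshold)
    if (length(regions) > 0L) {
        g <- hits(track)
        allStarts <- GRanges(seqnames(g), IRanges(start(g), width = 1L),
                             score = mcols(g)$score)
        regions <- .annotateKurtosis(regions, allStarts, kurtosisMax)
        regions <- regions[mcols(regions)$kurtosisPass]
    }
    if (length(regions) == 0L)
        stop("no preliminary enriched regions for sample '",
             sampleId(track), "': insufficient enrichment to estimate a ",
             "strand shift")
    ord <- order(mcols(regions)$hitCount, decreasing = TRUE)
    regions <- regions[ord[seq_len(min(topN, length(regions)))]]
    list(regions = regions, fwd = fwd, rev = rev)
}

#' Estimate the sample-wide strand shift
#'
#' For each candidate region and every integer shift s on the grid, the
#' Pearson correlation between the forward profile translated +s and the
#' reverse profile translated -s is evaluated over the region's span
#' extended by \code{maxShift} on both sides (so shifted profiles stay
#' in-window). Each region's correlation-maximizing shift votes, the
#' votes are kernel-smoothed over the shift grid (Epanechnikov, bandwidth
#' \code{curveBw}), and the global maximum of that curve is the
#' sample-wide shift. Ties break toward the smaller shift. Regions whose
#' best correlation falls below \code{minCorr} do not vote; regions with
#' zero variance on either strand are skipped.
#'
#' @param fwd,rev the sample's strand \linkS4class{DensityProfile}s.
#' @param regions candidate \code{GRanges} from
#'   \code{\link{preliminaryRegions}}.
#' @param minShift,maxShift integer shift grid bounds in bp (defaults 25
#'   and 150).
#' @param curveBw bandwidth for smoothing the vote distribution
#'   (default 5).
#' @param minCorr minimum best correlation for a region to vote
#'   (default 0.3).
#' @param id sample identifier recorded in the estimate.
#' @return A \linkS4class{ShiftEstimate}.
#' @export
estimateShift <- function(fwd, rev, regions, minShift = 25L,
                          maxShift = 150L, curveBw = 5, minCorr = 0.3,
                          id = "sample") {
    minShift <- as.integer(minShift); maxShift <- as.integer(maxShift)
    stopifnot(minShift <= maxShift)
    if (length(regions) == 0L) stop("no regions to estimate shift from")
    grid <- minShift:maxShift
    best <- rep(NA_integer_, length(regions))
    bestCor <- rep(NA_real_, length(regions))
    for (i in seq_along(regions)) {
        chrom <- as.character(seqnames(regions)[i])
        v <- fwd@values[[chrom]]
        L <- length(v)
        a <- max(1L, start(regions)[i] - maxShift)
        b <- min(L, end(regions)[i] + maxShift)
        off <- max(1L, a - maxShift) - 1L
        hi <- min(L, b + maxShift)
        Fv <- as.numeric(S4Vectors::window(fwd@values[[chrom]],
                                           off + 1L, hi))
        Rv <- as.numeric(S4Vectors::window(rev@values[[chrom]],
                                           off + 1L, hi))
        cors <- vapply(grid, function(s) {
            i1 <- max(a, off + 1L + s)
            i2 <- min(b, off + length(Fv) - s)
            if (i2 - i1 < 2L) return(NA_real_)
            x <- Fv[(i1:i2) - s - off]
            y <- Rv[(i1:i2) + s - off]
            if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
            stats::cor(x, y)
        }, numeric(1))
        if (all(is.na(cors))) {
            message("region ", chrom, ":", start(regions)[i], "-",
                    end(regions)[i],
                    " skipped (zero strand variance)")
            next
        }
        best[i] <- grid[which.max(cors)]   # first max = smaller shift
        bestCor[i] <- max(cors, na.rm = TRUE)
    }
    voted <- !is.na(best) & bestCor >= minCorr
    if (!any(!is.na(best)))
        stop("all candidate regions skipped; cannot estimate shift")
    votes <- if (any(voted)) best[voted] else best[!is.na(best)]
    curve <- vapply(grid, function(t)
        sum(epanechnikovKernel((t - votes) / curveBw)), numeric(1))
    s <- grid[which.max(curve)]            # ties toward the smaller shift
    new("ShiftEstimate", sampleId = id, shift = as.integer(s),
        perRegion = data.frame(
            chrom = as.character(seqnames(regions)),
            start = start(regions), end = end(regions),
            bestShift = best, maxCorr = bestCor, voted = voted),
        curve = data.frame(shift = grid, density = curve),
        nRegionsUsed = sum(voted))
}

#' One-call per-sample shift estimation
#'
#' Convenience wrapper: preliminary regions (bandwidth 50 nt, fold 25,
#' kurtosis 50, top 1000) followed by \code{\link{estimateShift}} on the
#' shift grid 25-150 nt with curve bandwidth 5 nt.
#'
#' @inheritParams preliminaryRegions
#' @inheritParams estimateShift
#' @return A \linkS4class{ShiftEstimate}.
#' @export
estimateSampleShift <- function(track, layout, h = 50, foldThreshold = 25,
                                kurtosisMax = 50, topN = 1000,
                                minShift = 25L, maxShift = 150L,
                                curveBw = 5, minCorr = 0.3) {
    prelim <- preliminaryRegions(track, layout, h, foldThreshold,
                                 kurtosisMax, topN)
    estimateShift(prelim$fwd, prelim$rev, prelim$regions, minShift,
                  maxShift, curveBw, minCorr, id = sampleId(track))
}

#' Infer shifts for negative controls
#'
#' Negative controls rarely yield enough preliminary regions for their
#' own estimate; each receives the median of the ChIP samples' shifts
#' (midpoint convention for an even number of samples, rounded to the
#' nearest integer).
#'
#' @param chipShifts integer vector of ChIP-sample shifts (bp).
#' @return The inferred control shift in bp.
#' @export
assignControlShift <- function(chipShifts) {
    if (length(chipShifts) == 0L)
        stop("no ChIP shift estimates to infer a control shift from")
    as.integer(round(stats::median(chipShifts)))
}
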