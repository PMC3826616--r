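#' @include AllClasses.R density.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

#' Call enriched regions from a pooled density profile
#'
#' A region is a maximal run of consecutive bases whose pooled density
#' H(i) strictly exceeds \code{foldThreshold} times the uniform
#' background b = total confident reads / effective genome size. Each
#' region is annotated with its peak position (leftmost argmax of the
#' pooled density) and peak height.
#'
#' @param pooled the pooled both-strand \linkS4class{DensityProfile}.
#' @param totalReads total retained read count over the samples that
#'   shaped the profile (controls excluded).
#' @param layout a \linkS4class{GenomeLayout} supplying the effective
#'   genome size.
#' @param foldThreshold fold enrichment over background (default 25).
#' @return A \code{GRanges} with \code{peakPos}, \code{peakHeight} and
#'   \code{background} metadata columns.
#' @export
callRegions <- function(pooled, totalReads, layout, foldThreshold = 25) {
    stopifnot(foldThreshold > 0)
    if (totalReads <= 0) stop("total read count must be positive")
    b <- totalReads / layout@effectiveGenomeSize
    thr <- foldThreshold * b
    out <- list()
    for (chrom in names(pooled@values)) {
        v <- pooled@values[[chrom]]
        views <- slice(v, lower = thr, includeLower = FALSE)
        if (length(views) == 0L) next
        pk <- viewWhichMaxs(views, na.rm = TRUE)   # leftmost tie
        gr <- GRanges(chrom, IRanges(start(views), end(views)),
                      peakPos = as.integer(pk),
                      peakHeight = as.numeric(viewMaxs(views)),
                      seqinfo = layout@seqinfo)
        out[[chrom]] <- gr
    }
    if (length(out) == 0L)
        return(GRanges(peakPos = integer(0), peakHeight = numeric(0),
                       background = numeric(0), seqinfo = layout@seqinfo))
    gr <- sort(do.call(c, unname(out)), ignore.strand = TRUE)
    mcols(gr)$background <- b
    gr
}

#' Excess kurtosis of read-start positions in a region
#'
#' Fisher (excess) kurtosis m4/m2^2 - 3 of the multiset of 5' start
#' positions, each position weighted by its hit count. Leptokurtic
#' regions (kurtosis above threshold) are technical artifacts, typically
#' single-position read stacks. Zero positional variance is defined as
#' +Inf so such stacks always fail the filter.
#'
#' @param pos integer positions with at least one hit.
#' @param counts parallel hit counts.
#' @param raw if \code{TRUE} report raw kurtosis (excess + 3).
#' @return A single numeric kurtosis value.
#' @export
regionKurtosis <- function(pos, counts = rep(1L, length(pos)), raw = FALSE) {
    if (length(pos) == 0L) stop("no hits in region")
    n <- sum(counts)
    mu <- sum(pos * counts) / n
    d <- pos - mu
    m2 <- sum(counts * d^2) / n
    if (m2 == 0) return(Inf)
    m4 <- sum(counts * d^4) / n
    k <- m4 / m2^2
    if (raw) k else k - 3
}

## Per-region kurtosis + contained-hit count against a set of width-1
## hit positions (pooled, already shifted). Returns the regions with
## 'kurtosis', 'hitCount' and 'kurtosisPass' metadata columns.
.annotateKurtosis <- function(regions, hitsGR, kurtosisMax = 50,
                              raw = FALSE) {
    k <- rep(NA_real_, length(regions))
    cnt <- integer(length(regions))
    if (length(hitsGR) > 0L && length(regions) > 0L) {
        ov <- findOverlaps(hitsGR, regions, ignore.strand = TRUE)
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        sc <- mcols(hitsGR)$score[qh]
        ps <- start(hitsGR)[qh]
        for (j in unique(sh)) {
            sel <- sh == j
            k[j] <- regionKurtosis(ps[sel], sc[sel], raw = raw)
            cnt[j] <- sum(sc[sel])
        }
    }
    mcols(regions)$kurtosis <- k
    mcols(regions)$hitCount <- cnt
    mcols(regions)$kurtosisPass <- !is.na(k) & k <= kurtosisMax
    regions
}

#' Pearson correlation between shifted strand profiles over regions
#'
#' For each region, the Pearson correlation between the (already
#' shift-corrected) forward- and reverse-strand densities over the region
#' span. Regions where either strand has zero variance get \code{NA} and
#' fail; low-correlation regions are artifacts.
#'
#' @param regions \code{GRanges} of called regions.
#' @param fwdValues,revValues \code{RleList} per-base strand densities,
#'   already translated by the sample shift(s).
#' @param minCorr pass threshold on r (default 0.3).
#' @return The regions with \code{strandCorr} and \code{strandCorrPass}
#'   metadata columns.
#' @export
annotateStrandCorrelation <- function(regions, fwdValues, revValues,
                                      minCorr = 0.3) {
    r <- rep(NA_real_, length(regions))
    for (i in seq_along(regions)) {
        chrom <- as.character(seqnames(regions)[i])
        if (!chrom %in% names(fwdValues)) next
        a <- start(regions)[i]; b <- end(regions)[i]
        x <- as.numeric(S4Vectors::window(fwdValues[[chrom]], a, b))
        y <- as.numeric(S4Vectors::window(revValues[[chrom]], a, b))
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        r[i] <- stats::cor(x, y)
    }
    mcols(regions)$strandCorr <- r
    mcols(regions)$strandCorrPass <- !is.na(r) & r >= minCorr
    regions
}

#' Structural region filters
#'
#' Removes regions on excluded chromosomes (sex chromosomes and the
#' mitochondrial genome by default), regions overlapping a blacklist
#' interval by >= 1 bp, and regions longer than \code{maxLen} bp
#' (strictly greater; a region of exactly \code{maxLen} is kept). The
#' operation is idempotent.
#'
#' @param regions \code{GRanges} of called regions.
#' @param layout a \linkS4class{GenomeLayout} with exclusion patterns and
#'   blacklist.
#' @param maxLen maximum region length in bp (default 500).
#' @return The surviving regions.
#' @export
applyStructuralFilters <- function(regions, layout, maxLen = 500) {
    if (length(regions) == 0L) return(regions)
    drop <- excludedChrom(as.character(seqnames(regions)),
                          layout@excludePattern)
    drop <- drop | width(regions) > maxLen
    if (length(layout@blacklist) > 0L)
        drop <- drop | countOverlaps(regions, layout@blacklist,
                                     ignore.strand = TRUE) > 0L
    regions[!drop]
}

#' Shift a hit track by its per-strand displacement
#'
#' Forward-strand hits move +s and reverse-strand hits -s, so both
#' pileups center on the binding site. Hits shifted off a chromosome end
#' are dropped.
#'
#' @param track a \linkS4class{HitTrack}.
#' @param s non-negative shift in bp.
#' @return A new \linkS4class{HitTrack} of shifted positions.
#' @export
shiftTrack <- function(track, s) {
    s <- as.integer(s)
    stopifnot(s >= 0L)
    g <- hits(track)
    if (length(g) == 0L || s == 0L) return(track)
    pos <- ifelse(as.character(strand(g)) == "+", start(g) + s,
                  start(g) - s)
    lim <- seqlengths(g)[as.character(seqnames(g))]
    keep <- pos >= 1L & (is.na(lim) | pos <= lim)
    new("HitTrack",
        hits = sort(GRanges(seqnames(g)[keep],
                            IRanges(pos[keep], width = 1L),
                            strand = strand(g)[keep],
                            score = mcols(g)$score[keep],
                            seqinfo = GenomeInfoDb::seqinfo(g)),
                    ignore.strand = TRUE),
        sample = track@sample)
}

.sampleInfoFrame <- function(samples) {
    DataFrame(sampleId = vapply(samples, function(s) s@sampleId, ""),
              target = vapply(samples, function(s) s@target, ""),
              cellType = vapply(samples, function(s) s@cellType, ""),
              lab = vapply(samples, function(s) s@lab, ""),
              replicate = vapply(samples, function(s) s@replicate, 1L),
              isControl = vapply(samples, function(s) s@isControl, TRUE),
              isHistone = vapply(samples, function(s) s@isHistone, TRUE),
              classId = vapply(samples, function(s) s@classId, ""))
}

#' Count shifted read starts of every sample within the called regions
#'
#' Each sample's 5' starts are translated by that sample's own shift
#' (forward +s, reverse -s) and counted inside each region (closed
#' interval in 1-based coordinates). Controls and histone marks are
#' counted here even though they never shaped the regions.
#'
#' @param regions \code{GRanges} of final regions.
#' @param tracks list of \linkS4class{HitTrack} objects (all samples).
#' @param shifts named integer vector of per-sample shifts; every track's
#'   \code{sampleId} must be present.
#' @return A \link[SummarizedExperiment]{RangedSummarizedExperiment} with
#'   an integer \code{counts} assay (regions x samples) and sample
#'   metadata in \code{colData}.
#' @export
countHits <- function(regions, tracks, shifts) {
    ids <- vapply(tracks, sampleId, "")
    missing <- setdiff(ids, names(shifts))
    if (length(missing) > 0L)
        stop("no shift assigned for sample(s): ",
             paste(missing, collapse = ", "))
    mat <- matrix(0L, nrow = length(regions), ncol = length(tracks),
                  dimnames = list(NULL, ids))
    for (j in seq_along(tracks)) {
        g <- hits(shiftTrack(tracks[[j]], shifts[[ids[j]]]))
        if (length(g) == 0L || length(regions) == 0L) next
        ov <- findOverlaps(g, regions, ignore.strand = TRUE)
        if (length(ov) == 0L) next
        sums <- rowsum(as.numeric(mcols(g)$score[S4Vectors::queryHits(ov)]),
                       S4Vectors::subjectHits(ov))
        mat[as.integer(rownames(sums)), j] <- as.integer(sums[, 1L])
    }
    names(regions) <- sprintf("region_%05d", seq_along(regions))
    rownames(mat) <- names(regions)
    SummarizedExperiment(assays = list(counts = mat),
                         rowRanges = regions,
                         colData = .sampleInfoFrame(
                             lapply(tracks, sampleInfo)))
}
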