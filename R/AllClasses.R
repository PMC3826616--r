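#' @import methods
#' @importFrom S4Vectors Rle RleList runValue runLength DataFrame metadata metadata<-
#' @importFrom IRanges IRanges Views slice viewWhichMaxs viewMaxs findOverlaps
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols mcols<- granges countOverlaps
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels keepSeqlevels
NULL

#' Sample metadata for one ChIP-seq library
#'
#' Describes a single sequencing library: the immunoprecipitated target,
#' cell type, producing lab, replicate number and its role in the analysis.
#' Negative controls (input, IgG, reverse-crosslinked chromatin) and
#' histone-mark libraries never shape the called regions; their reads are
#' only counted within regions called from the transcription-factor
#' samples. Replicates of the same target from different labs form
#' separate normalization classes, encoded in \code{classId}.
#'
#' @slot sampleId unique library identifier
#' @slot target name of the ChIPped protein (or control type)
#' @slot cellType cell line or tissue
#' @slot lab producing laboratory
#' @slot replicate replicate number (>= 1)
#' @slot isControl negative-control flag
#' @slot isHistone histone-mark flag (counted but never calls regions)
#' @slot classId grouping key for dispersion-estimation classes
#' @exportClass SampleInfo
setClass("SampleInfo", slots = c(
    sampleId  = "character",
    target    = "character",
    cellType  = "character",
    lab       = "character",
    replicate = "integer",
    isControl = "logical",
    isHistone = "logical",
    classId   = "character"
))

setValidity("SampleInfo", function(object) {
    msg <- NULL
    if (length(object@sampleId) != 1L || is.na(object@sampleId) ||
        !nzchar(object@sampleId))
        msg <- c(msg, "'sampleId' must be a single non-empty string")
    if (length(object@replicate) != 1L || is.na(object@replicate) ||
        object@replicate < 1L)
        msg <- c(msg, "'replicate' must be a single integer >= 1")
    if (length(object@isControl) != 1L || is.na(object@isControl))
        msg <- c(msg, "'isControl' must be TRUE or FALSE")
    if (is.null(msg)) TRUE else msg
})

#' Construct sample metadata
#'
#' @param sampleId unique library identifier.
#' @param target ChIPped protein name, or the control type for controls.
#' @param cellType,lab free-text annotations.
#' @param replicate replicate number, an integer >= 1.
#' @param isControl \code{TRUE} for negative controls.
#' @param isHistone \code{TRUE} for histone-mark ChIP; like controls these
#'   are counted within regions but never contribute to region calling.
#' @param classId normalization-class key; defaults to
#'   \code{target:cellType:lab} so replicates from different labs fall in
#'   separate classes.
#' @return A \linkS4class{SampleInfo} object.
#' @examples
#' SampleInfo("gata1_r1", target = "GATA1", cellType = "K562", lab = "labA")
#' @export
SampleInfo <- function(sampleId, target = "unknown", cellType = "NA",
                       lab = "NA", replicate = 1L, isControl = FALSE,
                       isHistone = FALSE,
                       classId = paste(target, cellType, lab, sep = ":")) {
    new("SampleInfo", sampleId = as.character(sampleId),
        target = as.character(target), cellType = as.character(cellType),
        lab = as.character(lab), replicate = as.integer(replicate),
        isControl = isControl, isHistone = isHistone,
        classId = as.character(classId))
}

#' Genome layout: chromosome sizes, exclusions and blacklist
#'
#' Holds the coordinate system region calling operates in: chromosome
#' lengths, name patterns for chromosomes excluded from the final region
#' set (sex chromosomes and the mitochondrial genome by default),
#' blacklisted intervals of known artifact-prone sequence, and the
#' effective genome size used for the uniform background rate
#' (total confident reads / genome size).
#'
#' @slot seqinfo a \link[GenomeInfoDb]{Seqinfo} with chromosome lengths
#' @slot excludePattern regular expressions matching excluded chromosomes
#' @slot blacklist \link[GenomicRanges]{GRanges} of artifact intervals
#' @slot effectiveGenomeSize background genome size in bp
#' @exportClass GenomeLayout
setClass("GenomeLayout", slots = c(
    seqinfo            = "Seqinfo",
    excludePattern     = "character",
    blacklist          = "GRanges",
    effectiveGenomeSize = "numeric"
))

setValidity("GenomeLayout", function(object) {
    msg <- NULL
    sl <- seqlengths(object@seqinfo)
    if (length(object@blacklist) > 0L) {
        bad <- !(as.character(seqnames(object@blacklist)) %in% names(sl))
        if (any(bad))
            msg <- c(msg, "blacklist intervals on undeclared chromosomes")
        else {
            ends <- end(object@blacklist)
            lim <- sl[as.character(seqnames(object@blacklist))]
            if (any(ends > lim))
                msg <- c(msg, "blacklist intervals extend past chromosome ends")
        }
    }
    keep <- !excludedChrom(names(sl), object@excludePattern)
    if (object@effectiveGenomeSize > sum(as.numeric(sl[keep])))
        msg <- c(msg,
            "effectiveGenomeSize exceeds total included chromosome length")
    if (object@effectiveGenomeSize <= 0)
        msg <- c(msg, "effectiveGenomeSize must be positive")
    if (is.null(msg)) TRUE else msg
})

excludedChrom <- function(chroms, patterns) {
    if (length(patterns) == 0L) return(rep(FALSE, length(chroms)))
    Reduce(`|`, lapply(patterns, grepl, x = chroms))
}

#' Construct a genome layout
#'
#' @param chromSizes named integer vector of chromosome lengths (bp), or a
#'   \link[GenomeInfoDb]{Seqinfo}.
#' @param excludePattern regular expressions; matching chromosomes are
#'   removed from the final region set. Defaults drop chrX, chrY and chrM.
#' @param blacklist \code{GRanges} of artifact intervals to subtract
#'   (any overlap of >= 1 bp disqualifies a region).
#' @param effectiveGenomeSize genome size for the uniform background rate;
#'   defaults to the summed length of non-excluded chromosomes.
#' @return A \linkS4class{GenomeLayout}.
#' @examples
#' GenomeLayout(c(chr1 = 1e6, chrM = 16571))
#' @export
GenomeLayout <- function(chromSizes,
                         excludePattern = c("^chrX$", "^chrY$", "^chrM$"),
                         blacklist = GRanges(),
                         effectiveGenomeSize = NULL) {
    si <- if (is(chromSizes, "Seqinfo")) chromSizes
          else Seqinfo(names(chromSizes), as.integer(chromSizes))
    sl <- seqlengths(si)
    if (is.null(effectiveGenomeSize)) {
        keep <- !excludedChrom(names(sl), excludePattern)
        effectiveGenomeSize <- sum(as.numeric(sl[keep]))
    }
    new("GenomeLayout", seqinfo = si, excludePattern = excludePattern,
        blacklist = blacklist, effectiveGenomeSize = effectiveGenomeSize)
}

#' Strand-specific 5' read-start track for one sample
#'
#' Sparse per-base counts of 5' read starts: each aligned read contributes
#' one hit at the 5'-most reference base of its alignment, on the
#' alignment's strand (for reverse-strand alignments the 5' end is the
#' rightmost aligned base). These counts are the C(j) input to kernel
#' density estimation.
#'
#' @slot hits width-1 \code{GRanges}, strand \code{+} or \code{-}, with a
#'   \code{score} column holding the hit count at that base
#' @slot sample the owning library's \linkS4class{SampleInfo}
#' @exportClass HitTrack
setClass("HitTrack", slots = c(hits = "GRanges", sample = "SampleInfo"))

setValidity("HitTrack", function(object) {
    h <- object@hits
    msg <- NULL
    if (length(h) > 0L) {
        if (is.null(mcols(h)$score) || any(mcols(h)$score < 1))
            msg <- c(msg, "hit counts must be >= 1 at stored positions")
        if (any(width(h) != 1L))
            msg <- c(msg, "hits must be width-1 positions")
        if (any(strand(h) == "*"))
            msg <- c(msg, "hits must be stranded")
        sl <- seqlengths(h)
        if (!all(is.na(sl))) {
            lim <- sl[as.character(seqnames(h))]
            if (any(!is.na(lim) & (start(h) < 1L | start(h) > lim)))
                msg <- c(msg, "hit positions outside chromosome bounds")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Kernel-smoothed read-start density profile
#'
#' Per-base density H(i): the kernel-weighted average of 5' read-start
#' counts within one bandwidth of each position, with the fixed
#' position-independent denominator sum(K(k/h), k = -h..h). Stored
#' run-length encoded per chromosome. A profile covers one strand, or
#' both after strand-shifted combination.
#'
#' @slot values \code{RleList}, one full-length \code{Rle} per chromosome
#' @slot strand "+", "-", or "*" for a combined strand-independent profile
#' @slot bandwidth kernel bandwidth h in bp
#' @slot shift the strand shift s (bp) already applied; 0 for raw strands
#' @exportClass DensityProfile
setClass("DensityProfile", slots = c(
    values    = "RleList",
    strand    = "character",
    bandwidth = "integer",
    shift     = "integer"
))

setValidity("DensityProfile", function(object) {
    msg <- NULL
    if (!object@strand %in% c("+", "-", "*"))
        msg <- c(msg, "strand must be '+', '-' or '*'")
    if (object@bandwidth < 1L)
        msg <- c(msg, "bandwidth must be >= 1")
    if (any(vapply(object@values, function(v) any(runValue(v) < 0),
                   logical(1))))
        msg <- c(msg, "density must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' Per-sample strand-shift estimate
#'
#' The sample-wide displacement s between forward- and reverse-strand
#' read-start pileups flanking binding sites (about half the sheared
#' fragment length). Derived from the correlation-maximizing shift in each
#' of the strongest preliminary regions, followed by kernel smoothing of
#' those per-region values over the shift grid.
#'
#' @slot sampleId library identifier
#' @slot shift the selected sample-wide shift (bp per strand)
#' @slot perRegion data.frame: region coordinates, argmax shift, max
#'   correlation, and whether the region voted
#' @slot curve data.frame of the smoothed shift density over the grid
#' @slot nRegionsUsed number of regions that voted
#' @exportClass ShiftEstimate
setClass("ShiftEstimate", slots = c(
    sampleId     = "character",
    shift        = "integer",
    perRegion    = "data.frame",
    curve        = "data.frame",
    nRegionsUsed = "integer"
))

#' Fitted partial least-squares regulation model
#'
#' A two-block PLS regression (SIMPLS) of gene-regulation readouts on
#' occupancy predictors, with the leave-one-out RMSEP curve used for
#' latent-variable selection and per-response cross-validated R-squared.
#'
#' @slot weights X projection weights (columns = components)
#' @slot xLoadings,yLoadings block loadings
#' @slot scores X scores of the training data
#' @slot coefficients regression coefficient array (p x q x ncomp), on the
#'   centered/scaled internal scale
#' @slot xCenter,xScale,yCenter,yScale autoscaling parameters
#' @slot ncomp selected number of latent variables
#' @slot rmsep LOO root-mean-squared error of prediction per component
#'   count, averaged over response columns, on the original response scale
#' @slot cvR2 per-response leave-one-out cross-validated R-squared at the
#'   selected component count
#' @slot variant "full" (controls + TF occupancy) or "null" (controls only)
#' @exportClass PLSModel
setClass("PLSModel", slots = c(
    weights      = "matrix",
    xLoadings    = "matrix",
    yLoadings    = "matrix",
    scores       = "matrix",
    coefficients = "array",
    xCenter      = "numeric",
    xScale       = "numeric",
    yCenter      = "numeric",
    yScale       = "numeric",
    ncomp        = "integer",
    rmsep        = "numeric",
    cvR2         = "numeric",
    variant      = "character"
))

setValidity("PLSModel", function(object) {
    msg <- NULL
    if (object@ncomp < 1L) msg <- c(msg, "ncomp must be >= 1")
    if (any(object@cvR2 > 1 + 1e-12)) msg <- c(msg, "CV R^2 cannot exceed 1")
    if (is.null(msg)) TRUE else msg
})
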