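#' @include AllClasses.R
NULL

#' Accessors for UniPeakR objects
#'
#' Small accessor generics: \code{sampleId} returns the library
#' identifier, \code{totalHits} the number of retained read starts in a
#' \linkS4class{HitTrack}, \code{hits} its position-level \code{GRanges},
#' \code{sampleInfo} the attached metadata, \code{strandShift} the
#' estimated per-strand shift, \code{profileValues} a profile's per-base
#' Rle values, and \code{bandwidth} its kernel bandwidth.
#'
#' @param x an object of the documented class.
#' @return See each method's description.
#' @name accessors
#' @aliases sampleId totalHits hits sampleInfo strandShift profileValues bandwidth
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("totalHits", function(x) standardGeneric("totalHits"))

#' @rdname accessors
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))

#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname accessors
#' @export
setGeneric("strandShift", function(x) standardGeneric("strandShift"))

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname accessors
#' @export
setGeneric("bandwidth", function(x) standardGeneric("bandwidth"))

#' @rdname accessors
setMethod("sampleId", "SampleInfo", function(x) x@sampleId)

#' @rdname accessors
setMethod("sampleId", "HitTrack", function(x) x@sample@sampleId)

#' @rdname accessors
setMethod("sampleId", "ShiftEstimate", function(x) x@sampleId)

#' @rdname accessors
setMethod("hits", "HitTrack", function(x) x@hits)

#' @rdname accessors
setMethod("sampleInfo", "HitTrack", function(x) x@sample)

#' @rdname accessors
setMethod("totalHits", "HitTrack",
          function(x) if (length(x@hits)) sum(mcols(x@hits)$score) else 0L)

#' @rdname accessors
setMethod("strandShift", "ShiftEstimate", function(x) x@shift)

#' @rdname accessors
setMethod("profileValues", "DensityProfile", function(x) x@values)

#' @rdname accessors
setMethod("bandwidth", "DensityProfile", function(x) x@bandwidth)

setMethod("show", "SampleInfo", function(object) {
    role <- if (object@isControl) "control"
            else if (object@isHistone) "histone" else "ChIP"
    cat("SampleInfo:", object@sampleId,
        sprintf("[%s, %s | %s, %s, rep %d | class %s]\n", role,
                object@target, object@cellType, object@lab,
                object@replicate, object@classId))
})

setMethod("show", "HitTrack", function(object) {
    cat(sprintf("HitTrack '%s': %d hits at %d positions on %d chromosome(s)\n",
                sampleId(object), totalHits(object), length(object@hits),
                length(unique(as.character(seqnames(object@hits))))))
})

setMethod("show", "GenomeLayout", function(object) {
    sl <- seqlengths(object@seqinfo)
    cat(sprintf(
        "GenomeLayout: %d chromosome(s), effective genome size %.0f bp, %d blacklist interval(s)\n",
        length(sl), object@effectiveGenomeSize, length(object@blacklist)))
})

setMethod("show", "DensityProfile", function(object) {
    cat(sprintf(
        "DensityProfile [strand %s, h = %d bp, shift %+d bp] over %d chromosome(s); total mass %.2f\n",
        object@strand, object@bandwidth, object@shift,
        length(object@values),
        sum(vapply(object@values, function(v) sum(as.numeric(v)),
                   numeric(1)))))
})

setMethod("show", "ShiftEstimate", function(object) {
    cat(sprintf(
        "ShiftEstimate '%s': shift = %d bp per strand (from %d region(s))\n",
        object@sampleId, object@shift, object@nRegionsUsed))
})

setMethod("show", "PLSModel", function(object) {
    cat(sprintf("PLSModel (%s): %d latent variable(s)\n", object@variant,
                object@ncomp))
    cat("  RMSEP by component:",
        paste(sprintf("%.4g", object@rmsep), collapse = " "), "\n")
    cat("  LOO CV R^2:",
        paste(sprintf("%s=%.3f", names(object@cvR2), object@cvR2),
              collapse = " "), "\n")
})
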