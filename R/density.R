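#' @include AllClasses.R
NULL

#' Epanechnikov (quadratic) kernel
#'
#' The kernel used for all read-start smoothing:
#' K(x) = (3/4)(1 - x^2) for |x| <= 1, and 0 otherwise.
#'
#' @param x numeric vector of dimensionless offsets.
#' @return Kernel weights, same length as \code{x}.
#' @examples
#' epanechnikovKernel(c(-1, 0, 0.5, 1))  # 0 0.75 0.5625 0
#' @export
epanechnikovKernel <- function(x) {
    ifelse(abs(x) <= 1, 0.75 * (1 - x^2), 0)
}

## Discrete kernel weights at integer offsets -h..h and the fixed,
## position-independent denominator sum(K(k/h)). No boundary
## renormalization: hits within h of a chromosome end lose the mass that
## falls off-chromosome.
.kernelWeights <- function(h) {
    off <- (-h):h
    w <- epanechnikovKernel(off / h)
    list(offsets = off, weights = w, denom = sum(w))
}

## Direct sparse convolution of a per-base count vector with the
## discrete Epanechnikov kernel. cnt is a dense window of C(j); returns
## H over the same window, positions indexed identically.
.smoothDense <- function(cnt, h) {
    kw <- .kernelWeights(h)
    n <- length(cnt)
    ## zero-pad so stats::filter (a compiled moving weighted sum with
    ## the symmetric kernel) is defined over the whole window
    padded <- c(numeric(h), cnt, numeric(h))
    H <- stats::filter(padded, kw$weights, method = "convolution",
                       sides = 2L)
    as.numeric(H[(h + 1L):(h + n)]) / kw$denom
}

.chromLengths <- function(gr) {
    sl <- seqlengths(gr)
    if (any(is.na(sl)))
        stop("chromosome lengths missing; attach a Seqinfo to the hits")
    sl
}

#' Kernel-smooth one strand of a hit track
#'
#' Computes the per-base density
#' H(i) = sum_{j=i-h..i+h} K((i-j)/h) C(j) / sum_{k=-h..h} K(k/h)
#' from the 5' read-start counts C(j) of one strand, by direct sparse
#' convolution. The denominator is fixed (position-independent), so each
#' hit at least h bp from a chromosome end contributes exactly unit mass
#' to the profile.
#'
#' @param track a \linkS4class{HitTrack}.
#' @param h integer kernel bandwidth in bp.
#' @param useStrand which strand's hits to smooth, \code{"+"} or
#'   \code{"-"}.
#' @return A \linkS4class{DensityProfile} (shift 0) covering every
#'   chromosome declared in the track's \code{Seqinfo}.
#' @export
smoothProfile <- function(track, h, useStrand = c("+", "-")) {
    useStrand <- match.arg(useStrand)
    h <- as.integer(h)
    stopifnot(h >= 1L)
    gr <- hits(track)
    sl <- .chromLengths(gr)
    gr <- gr[strand(gr) == useStrand]
    vals <- lapply(names(sl), function(chrom) {
        L <- sl[[chrom]]
        g <- gr[seqnames(gr) == chrom]
        if (length(g) == 0L) return(Rle(0, L))
        pos <- start(g)
        cnt <- mcols(g)$score
        a <- max(1L, min(pos) - h)
        b <- min(L, max(pos) + h)
        win <- numeric(b - a + 1L)
        idx <- pos - a + 1L
        win[idx] <- win[idx] + cnt   # positions are unique in a HitTrack
        Hw <- .smoothDense(win, h)
        c(Rle(0, a - 1L), Rle(Hw), Rle(0, L - b))
    })
    names(vals) <- names(sl)
    new("DensityProfile", values = as(vals, "RleList"), strand = useStrand,
        bandwidth = h, shift = 0L)
}

## Translate an Rle by s bases (positive = rightward / 3'-ward on the
## reference), padding with zeros and truncating at the ends.
.shiftRle <- function(v, s) {
    L <- length(v)
    s <- as.integer(s)
    if (s == 0L) return(v)
    if (abs(s) >= L) return(Rle(0, L))
    if (s > 0L) c(Rle(0, s), S4Vectors::window(v, 1L, L - s))
    else c(S4Vectors::window(v, 1L - s, L), Rle(0, -s))
}

#' Combine strand profiles into a unified strand-independent profile
#'
#' Translates the forward-strand profile +s (3'-ward) and the
#' reverse-strand profile -s, then sums them positionwise, so that the
#' two read-start pileups flanking each binding site coincide at its
#' center.
#'
#' @param fwd,rev forward- and reverse-strand \linkS4class{DensityProfile}
#'   objects with equal bandwidths and chromosomes.
#' @param s non-negative per-strand shift in bp.
#' @return A both-strand \linkS4class{DensityProfile} recording \code{s}.
#' @export
combineProfiles <- function(fwd, rev, s) {
    s <- as.integer(s)
    stopifnot(s >= 0L)
    if (bandwidth(fwd) != bandwidth(rev))
        stop("cannot combine profiles with different bandwidths")
    if (!identical(names(fwd@values), names(rev@values)))
        stop("profiles cover different chromosomes")
    vals <- lapply(names(fwd@values), function(chrom) {
        .shiftRle(fwd@values[[chrom]], s) + .shiftRle(rev@values[[chrom]], -s)
    })
    names(vals) <- names(fwd@values)
    new("DensityProfile", values = as(vals, "RleList"), strand = "*",
        bandwidth = bandwidth(fwd), shift = s)
}

#' Pool unified profiles across samples
#'
#' Positionwise sum of per-sample profiles; the pooled profile is the
#' single underlying density that region calling operates on. Negative
#' controls and histone-mark samples must not be included (they never
#' shape regions); the caller enforces this.
#'
#' @param profiles a non-empty list of \linkS4class{DensityProfile}
#'   objects with equal bandwidths over the same chromosomes.
#' @return The summed \linkS4class{DensityProfile}.
#' @export
pooledProfile <- function(profiles) {
    if (length(profiles) == 0L)
        stop("no profiles to pool")
    h <- unique(vapply(profiles, bandwidth, integer(1)))
    if (length(h) != 1L)
        stop("profiles have differing bandwidths")
    out <- profiles[[1L]]
    if (length(profiles) > 1L) {
        vals <- out@values
        for (p in profiles[-1L]) {
            if (!identical(names(p@values), names(vals)))
                stop("profiles cover different chromosomes")
            vals <- vals + p@values
        }
        out@values <- vals
    }
    out@strand <- "*"
    out
}

#' Export a density profile as bedGraph
#'
#' Writes the run-length blocks of a profile as a four-column bedGraph
#' (0-based half-open, as the format requires) for genome-browser
#' inspection. Zero runs are omitted.
#'
#' @param profile a \linkS4class{DensityProfile}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
exportProfileBedGraph <- function(profile, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (chrom in names(profile@values)) {
        v <- profile@values[[chrom]]
        ends <- cumsum(runLength(v))
        starts <- ends - runLength(v) + 1L
        keep <- runValue(v) != 0
        if (!any(keep)) next
        writeLines(sprintf("%s\t%d\t%d\t%.6g", chrom,
                           starts[keep] - 1L, ends[keep],
                           runValue(v)[keep]), con)
    }
    invisible(path)
}
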