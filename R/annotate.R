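#' @include reads-io.R
#' @importFrom Biostrings DNAStringSet letterFrequency vcountPattern subseq reverseComplement width
NULL

#' Match region peaks to the nearest point features
#'
#' For each region peak, the nearest feature within \code{maxDist} bp is
#' assigned (none if the closest lies strictly farther). Exact distance
#' ties resolve to the feature with the smaller coordinate. The signed
#' distance is feature minus peak, flipped for minus-strand features, so
#' a negative value always means the feature lies upstream of the peak on
#' the feature's own strand; strand is ignored for the distance itself.
#'
#' @param peaks \code{GRanges} of region peak positions (width 1, or any
#'   ranges carrying a \code{peakPos} column), or an integer vector of
#'   positions with \code{chrom}.
#' @param features \code{GRanges} of point features (width-1; CAGE/TSS
#'   features may carry strand).
#' @param maxDist maximum match distance in bp (default 500).
#' @return A \code{DataFrame} with \code{matched}, \code{featureIndex},
#'   \code{distance} (signed) and \code{featureStrand}.
#' @export
matchNearest <- function(peaks, features, maxDist = 500) {
    pkPos <- if (!is.null(mcols(peaks)$peakPos)) mcols(peaks)$peakPos
             else start(peaks)
    pkChrom <- as.character(seqnames(peaks))
    n <- length(pkPos)
    out <- DataFrame(matched = logical(n),
                     featureIndex = rep(NA_integer_, n),
                     distance = rep(NA_integer_, n),
                     featureStrand = rep(NA_character_, n))
    fChrom <- as.character(seqnames(features))
    for (chrom in unique(pkChrom)) {
        fi <- which(fChrom == chrom)
        if (length(fi) == 0L) next
        fpos <- start(features)[fi]
        ord <- order(fpos)
        fi <- fi[ord]; fpos <- fpos[ord]
        pi <- which(pkChrom == chrom)
        lo <- findInterval(pkPos[pi], fpos)
        for (k in seq_along(pi)) {
            p <- pkPos[pi[k]]
            cand <- c(if (lo[k] >= 1L) lo[k],
                      if (lo[k] < length(fpos)) lo[k] + 1L)
            if (length(cand) == 0L) next
            d <- abs(fpos[cand] - p)
            best <- cand[which.min(d)]      # tie -> smaller coordinate
            if (min(d) > maxDist) next
            j <- fi[best]
            str <- as.character(strand(features)[j])
            raw <- start(features)[j] - p
            signed <- if (identical(str, "-")) -raw else raw
            out$matched[pi[k]] <- TRUE
            out$featureIndex[pi[k]] <- j
            out$distance[pi[k]] <- as.integer(signed)
            out$featureStrand[pi[k]] <- str
        }
    }
    out
}

#' Consensus-promoter labels
#'
#' A region is a consensus promoter when its density peak lies within the
#' match distance of all three promoter evidence classes simultaneously:
#' an initiating Pol II (S5P) peak, a CAGE peak, and an annotated TSS.
#'
#' @param polII,cage,tss match results from \code{\link{matchNearest}}
#'   for the three feature classes, over the same regions.
#' @return Logical vector, one flag per region.
#' @export
consensusLabel <- function(polII, cage, tss) {
    stopifnot(nrow(polII) == nrow(cage), nrow(cage) == nrow(tss))
    polII$matched & cage$matched & tss$matched
}

#' GC fraction and CpG rate of region sequence
#'
#' \code{gcFraction} is (G+C) over called A/C/G/T bases (soft-masked
#' lowercase counts; N excluded from the denominator); \code{cpgRate} is
#' the count of CG dinucleotides divided by (length - 1). All-N regions
#' give \code{NA}.
#'
#' @param regions \code{GRanges}.
#' @param genome a named \code{DNAStringSet} of chromosome sequences.
#' @return \code{DataFrame} with \code{gcFraction} and \code{cpgRate}.
#' @export
sequenceComposition <- function(regions, genome) {
    seqs <- DNAStringSet(vapply(seq_along(regions), function(i) {
        chrom <- as.character(seqnames(regions)[i])
        toupper(as.character(subseq(genome[[chrom]],
                                    start(regions)[i], end(regions)[i])))
    }, ""))
    acgt <- letterFrequency(seqs, c("A", "C", "G", "T"))
    called <- rowSums(acgt)
    gc <- ifelse(called > 0, (acgt[, "C"] + acgt[, "G"]) / called,
                 NA_real_)
    cpg <- ifelse(called > 0,
                  vcountPattern("CG", seqs) / (width(seqs) - 1),
                  NA_real_)
    DataFrame(gcFraction = gc, cpgRate = cpg)
}

#' Fraction of evolutionarily constrained positions
#'
#' The proportion of scored positions in each region whose rejected
#' substitution (RS) score strictly exceeds \code{rsMin}; positions
#' without a score are excluded from the denominator, and a region with
#' no scored positions is \code{NA}.
#'
#' @param regions \code{GRanges}.
#' @param scores score track \code{GRanges} from
#'   \code{\link{loadScoreTrack}}.
#' @param rsMin strict threshold (default 2).
#' @return Numeric vector of proportions (or \code{NA}).
#' @export
constraintFraction <- function(regions, scores, rsMin = 2) {
    vapply(seq_along(regions), function(i) {
        ov <- findOverlaps(regions[i], scores, ignore.strand = TRUE)
        if (length(ov) == 0L) return(NA_real_)
        sub <- scores[S4Vectors::subjectHits(ov)]
        inter <- GenomicRanges::pintersect(
            rep(granges(regions[i]), length(sub)), granges(sub),
            ignore.strand = TRUE)
        covered <- sum(width(inter))
        above <- sum(width(inter)[mcols(sub)$score > rsMin])
        above / covered
    }, numeric(1))
}

#' Count elongating Pol II read starts over a gene body
#'
#' Unshifted 5' starts within the closed window from \code{pad} bp
#' upstream of the TSS to \code{pad} bp downstream of the TES of the
#' longest isoform, strand-aware (upstream/downstream flip for
#' minus-strand genes; with symmetric padding the window is
#' [start - pad, end + pad] either way).
#'
#' @param track the elongating Pol II \linkS4class{HitTrack}.
#' @param genes \code{GRanges} of genes (one range per gene, longest
#'   isoform; see \code{\link{longestIsoform}}).
#' @param pad bp of padding (default 100).
#' @return Integer vector of read counts per gene.
#' @export
geneBodyCount <- function(track, genes, pad = 100) {
    if (any(end(genes) < start(genes)))
        stop("gene with TES before TSS after strand resolution")
    win <- GRanges(seqnames(genes),
                   IRanges(pmax(1L, start(genes) - pad),
                           end(genes) + pad))
    g <- hits(track)
    counts <- integer(length(genes))
    if (length(g) == 0L) return(counts)
    ov <- findOverlaps(g, win, ignore.strand = TRUE)
    if (length(ov) == 0L) return(counts)
    sums <- rowsum(as.numeric(mcols(g)$score[S4Vectors::queryHits(ov)]),
                   S4Vectors::subjectHits(ov))
    counts[as.integer(rownames(sums))] <- as.integer(sums[, 1L])
    counts
}

#' Longest isoform per gene
#'
#' @param transcripts \code{GRanges} of transcripts with a
#'   \code{gene_id} metadata column.
#' @return One range per gene: the transcript with the greatest
#'   reference span (ties: the first).
#' @export
longestIsoform <- function(transcripts) {
    gid <- mcols(transcripts)$gene_id
    if (is.null(gid)) stop("transcripts need a 'gene_id' column")
    sel <- vapply(split(seq_along(transcripts), gid), function(ix)
        ix[which.max(width(transcripts)[ix])], integer(1))
    transcripts[sort(sel)]
}
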