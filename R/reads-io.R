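#' @include AllClasses.R
#' @importFrom Rsamtools scanBam ScanBamParam scanBamFlag
#' @importFrom utils read.table write.table
NULL

#' Map an alignment-confidence posterior to a MAPQ cutoff
#'
#' Aligners encode confidence as MAPQ = -10 log10(P(error)), so requiring
#' a posterior probability of correctness >= p is equivalent to requiring
#' MAPQ >= -10 log10(1 - p). A posterior of 0.9 corresponds to MAPQ 10.
#'
#' @param minPosterior required posterior probability, in (0, 1).
#' @return The smallest integer MAPQ satisfying the posterior bound.
#' @examples
#' mapqFromPosterior(0.9)  # 10
#' @export
mapqFromPosterior <- function(minPosterior) {
    stopifnot(minPosterior > 0, minPosterior < 1)
    as.integer(ceiling(-10 * log10(1 - minPosterior) - 1e-9))
}

## Reference-consumed width of a CIGAR string (ops M, D, N, =, X).
.cigarRefWidth <- function(cigar) {
    m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)
    vapply(seq_along(cigar), function(i) {
        ops <- regmatches(cigar[i], m[i])[[1L]]
        if (length(ops) == 0L) return(NA_integer_)
        len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
        op <- sub("^\\d+", "", ops)
        sum(len[op %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
}

## Aggregate duplicate (chrom, pos, strand) hits into count-weighted
## width-1 GRanges with the layout's Seqinfo.
.aggregateHits <- function(chrom, pos, strand, counts, layout) {
    key <- paste(chrom, pos, strand, sep = "\r")
    agg <- rowsum(as.numeric(counts), key, reorder = FALSE)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    chrom <- vapply(parts, `[`, character(1), 1L)
    pos <- as.integer(vapply(parts, `[`, character(1), 2L))
    str <- vapply(parts, `[`, character(1), 3L)
    gr <- GRanges(chrom, IRanges(pos, width = 1L), strand = str,
                  score = as.integer(agg[, 1L]),
                  seqinfo = layout@seqinfo)
    sort(gr, ignore.strand = TRUE)
}

#' Build a hit track from explicit read-start positions
#'
#' @param chrom,pos,readStrand parallel vectors of chromosome, 1-based
#'   5' start position and strand ("+"/"-") per read.
#' @param layout a \linkS4class{GenomeLayout} providing the coordinate
#'   system.
#' @param sample the library's \linkS4class{SampleInfo}.
#' @param counts optional per-record multiplicities (default 1 each).
#' @return A \linkS4class{HitTrack}; duplicate positions are aggregated
#'   into counts.
#' @export
hitTrackFromPositions <- function(chrom, pos, readStrand, layout, sample,
                                  counts = rep(1L, length(pos))) {
    known <- chrom %in% seqlevels(layout@seqinfo)
    if (!all(known)) {
        message(sum(!known), " record(s) on unknown chromosomes rejected")
        chrom <- chrom[known]; pos <- pos[known]
        readStrand <- readStrand[known]; counts <- counts[known]
    }
    if (length(pos) == 0L)
        return(new("HitTrack",
                   hits = GRanges(seqinfo = layout@seqinfo),
                   sample = sample))
    new("HitTrack",
        hits = .aggregateHits(chrom, pos, readStrand, counts, layout),
        sample = sample)
}

#' Load 5' read starts from a BAM file
#'
#' Each retained alignment yields one hit at its 5'-most reference base:
#' the leftmost aligned base for forward-strand alignments, the rightmost
#' for reverse-strand alignments. The confidence filter "posterior
#' probability >= minPosterior" is enforced through MAPQ (see
#' \code{\link{mapqFromPosterior}}); unmapped and (by default) secondary
#' or supplementary records are dropped. Reads are consumed as aligned:
#' any truncation to a common read length is an upstream responsibility,
#' noted once per load.
#'
#' @param path BAM file.
#' @param layout a \linkS4class{GenomeLayout}; alignments on chromosomes
#'   it does not declare are rejected and counted in a message.
#' @param sample the library's \linkS4class{SampleInfo}.
#' @param minPosterior required alignment posterior (default 0.9).
#' @param includeSecondary keep secondary/supplementary alignments.
#' @param collapseDuplicates if \code{TRUE}, count each (position, strand)
#'   at most once. Off by default: duplicate reads are retained.
#' @return A \linkS4class{HitTrack}.
#' @export
readHitsBam <- function(path, layout, sample, minPosterior = 0.9,
                        includeSecondary = FALSE,
                        collapseDuplicates = FALSE) {
    if (!file.exists(path)) stop("cannot read BAM file: ", path)
    p <- ScanBamParam(what = c("rname", "pos", "strand", "mapq", "cigar"),
                      flag = scanBamFlag(isUnmappedQuery = FALSE))
    res <- tryCatch(scanBam(path, param = p)[[1L]],
                    error = function(e) stop("unreadable BAM file: ", path,
                                             " (", conditionMessage(e), ")"))
    message("consuming alignments as given; read-length truncation, ",
            "if any, happens upstream")
    keep <- !is.na(res$mapq) & res$mapq >= mapqFromPosterior(minPosterior)
    chrom <- as.character(res$rname)[keep]
    pos <- res$pos[keep]
    str <- as.character(res$strand)[keep]
    refw <- .cigarRefWidth(res$cigar[keep])
    pos5 <- ifelse(str == "-", pos + refw - 1L, pos)
    tr <- hitTrackFromPositions(chrom, pos5, str, layout, sample)
    if (collapseDuplicates && length(hits(tr)) > 0L)
        mcols(tr@hits)$score <- 1L
    tr
}

#' Load 5' read starts from a BED file
#'
#' Accepts either single-base intervals of pre-computed 5' starts or full
#' alignment intervals; in both cases the 5' end per strand is used
#' (start for \code{+}, end for \code{-}).
#'
#' @inheritParams readHitsBam
#' @param path BED file with at least chrom/start/end/name/score/strand
#'   columns (strand defaults to \code{+} if absent).
#' @param scoreIsCount if \code{TRUE}, the BED score column is a hit
#'   multiplicity (the convention \code{\link{writeHitsBed}} uses), so a
#'   write/reload round trip reproduces the track exactly.
#' @return A \linkS4class{HitTrack}.
#' @export
readHitsBed <- function(path, layout, sample, scoreIsCount = FALSE,
                        collapseDuplicates = FALSE) {
    gr <- loadIntervals(path)
    counts <- if (scoreIsCount && !is.null(mcols(gr)$score))
        as.integer(mcols(gr)$score) else rep(1L, length(gr))
    str <- as.character(strand(gr))
    str[str == "*"] <- "+"
    pos5 <- ifelse(str == "-", end(gr), start(gr))
    tr <- hitTrackFromPositions(as.character(seqnames(gr)), pos5, str,
                                layout, sample, counts = counts)
    if (collapseDuplicates && length(hits(tr)) > 0L)
        mcols(tr@hits)$score <- 1L
    tr
}

#' Write a hit track as BED of single-base intervals
#'
#' One line per stored position with the hit count in the score column;
#' reloading with \code{\link{readHitsBed}} reproduces the track exactly
#' (the count is re-expanded from the score).
#'
#' @param track a \linkS4class{HitTrack}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeHitsBed <- function(track, path) {
    g <- hits(track)
    df <- data.frame(chrom = as.character(seqnames(g)),
                     start = start(g) - 1L, end = start(g),
                     name = sampleId(track), score = mcols(g)$score,
                     strand = as.character(strand(g)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Load a BED-like interval file
#'
#' Parses 3-6 column BED (0-based half-open on disk) into a sorted
#' 1-based \code{GRanges}. Records with end <= start are rejected with a
#' warning; track/browser lines are skipped.
#'
#' @param path BED-like file.
#' @return A \code{GRanges} sorted by (chromosome, start), with
#'   name/score/strand columns when present.
#' @export
loadIntervals <- function(path) {
    if (!file.exists(path)) stop("cannot read interval file: ", path)
    lines <- readLines(path)
    lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
    if (length(lines) == 0L) return(GRanges())
    fields <- strsplit(lines, "[ \t]+")
    if (min(lengths(fields)) < 3L)
        stop("malformed BED: fewer than 3 columns")
    col <- function(k) vapply(fields, function(f)
        if (length(f) >= k) f[k] else NA_character_, character(1))
    chrom <- col(1L)
    start0 <- suppressWarnings(as.numeric(col(2L)))
    end0 <- suppressWarnings(as.numeric(col(3L)))
    if (any(is.na(start0)) || any(is.na(end0)))
        stop("malformed BED: non-numeric coordinates")
    bad <- end0 <= start0
    if (any(bad)) {
        warning(sum(bad), " record(s) with end <= start skipped")
        fields <- fields[!bad]; chrom <- chrom[!bad]
        start0 <- start0[!bad]; end0 <- end0[!bad]
    }
    if (length(chrom) == 0L) return(GRanges())
    gr <- GRanges(chrom, IRanges(start0 + 1, end0))
    ncol <- max(lengths(fields))
    if (ncol >= 4L) mcols(gr)$name <- col(4L)
    if (ncol >= 5L)
        mcols(gr)$score <- suppressWarnings(as.numeric(col(5L)))
    if (ncol >= 6L) {
        str <- col(6L)
        str[is.na(str) | !str %in% c("+", "-")] <- "*"
        strand(gr) <- str
    }
    sort(gr, ignore.strand = TRUE)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path whitespace-separated file of chromosome name and length.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    tab <- read.table(path, header = FALSE,
                      col.names = c("chrom", "size"),
                      colClasses = c("character", "integer"))
    stats::setNames(tab$size, tab$chrom)
}

#' Load a per-base score track (bedGraph or wig)
#'
#' Scores cover exactly the positions the records span; positions with no
#' record are missing, not zero. Overlapping records with conflicting
#' values are a fatal error (overlaps with identical values are merged).
#'
#' @param path bedGraph or wiggle file (format chosen by
#'   \code{rtracklayer} from the extension/content).
#' @return A \code{GRanges} with a numeric \code{score} column.
#' @export
loadScoreTrack <- function(path) {
    fmt <- if (grepl("\\.(wig|wiggle)(\\.gz)?$", path, ignore.case = TRUE))
        "wig" else "bedGraph"
    gr <- rtracklayer::import(path, format = fmt)
    ov <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE,
                       ignore.strand = TRUE)
    if (length(ov) > 0L) {
        sA <- mcols(gr)$score[S4Vectors::queryHits(ov)]
        sB <- mcols(gr)$score[S4Vectors::subjectHits(ov)]
        if (any(sA != sB))
            stop("overlapping score records with conflicting values")
    }
    sort(gr, ignore.strand = TRUE)
}
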