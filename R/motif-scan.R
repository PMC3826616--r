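#' @include annotate.R
NULL

#' Read position weight matrices in MEME minimal format
#'
#' Parses the letter-probability matrices of a MEME-style motif file
#' (\code{MOTIF name} headers followed by a
#' \code{letter-probability matrix} block, rows = positions over A/C/G/T).
#'
#' @param path MEME-format file.
#' @return Named list of 4 x width probability matrices (rows A,C,G,T).
#' @export
readMemeMotifs <- function(path) {
    lines <- readLines(path)
    motifs <- list()
    i <- 1L
    while (i <= length(lines)) {
        if (grepl("^MOTIF\\s", lines[i])) {
            nm <- strsplit(trimws(lines[i]), "\\s+")[[1L]][2L]
            j <- i + 1L
            while (j <= length(lines) &&
                   !grepl("^letter-probability matrix", lines[j]))
                j <- j + 1L
            if (j > length(lines)) break
            rows <- list()
            k <- j + 1L
            while (k <= length(lines) &&
                   grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$",
                         lines[k])) {
                rows[[length(rows) + 1L]] <-
                    as.numeric(strsplit(trimws(lines[k]), "\\s+")[[1L]])
                k <- k + 1L
            }
            m <- t(do.call(rbind, rows))
            rownames(m) <- c("A", "C", "G", "T")
            motifs[[nm]] <- m
            i <- k
        } else i <- i + 1L
    }
    if (length(motifs) == 0L) stop("no motifs found in ", path)
    motifs
}

## Integer-discretized log2-odds scores against a uniform 0.25
## background. Probabilities are floored and renormalized so log-odds
## stay finite.
.pwmIntScores <- function(pwm, scale = 1000, floorProb = 1e-4) {
    pwm <- pmax(pwm, floorProb)
    pwm <- sweep(pwm, 2L, colSums(pwm), "/")
    round(log2(pwm / 0.25) * scale)
}

## Exact null distribution of the discretized motif score under an iid
## uniform background, by dynamic programming over PWM columns.
.pwmNullDistribution <- function(lodInt) {
    probs <- 1
    offset <- 0L
    for (j in seq_len(ncol(lodInt))) {
        col <- lodInt[, j]
        lo <- min(col)
        n <- length(probs)
        newp <- numeric(n + max(col) - lo)
        for (b in 1:4) {
            sh <- col[b] - lo
            idx <- (1:n) + sh
            newp[idx] <- newp[idx] + 0.25 * probs
        }
        probs <- newp
        offset <- offset + lo
    }
    ## tailP[i] = P(S >= offset + i - 1)
    tailP <- rev(cumsum(rev(probs)))
    list(probs = probs, offset = offset, tailP = tailP)
}

## P(S >= scoreInt) under the null distribution.
.pwmPValue <- function(null, scoreInt) {
    i <- scoreInt - null$offset + 1L
    n <- length(null$tailP)
    ifelse(i <= 1L, 1, ifelse(i > n, 0, null$tailP[pmax(i, 1L)]))
}

.dnaCodes <- function(s) {
    match(strsplit(toupper(s), "")[[1L]], c("A", "C", "G", "T"))
}

## Best (maximum) discretized score of a motif over every offset of a
## coded sequence; windows containing non-ACGT bases are skipped.
.bestMotifScore <- function(codes, lodInt) {
    w <- ncol(lodInt)
    n <- length(codes) - w + 1L
    if (n < 1L) return(NA_integer_)
    best <- NA_integer_
    sc <- rep(0L, n)
    ok <- rep(TRUE, n)
    for (k in seq_len(w)) {
        ck <- codes[k:(k + n - 1L)]
        bad <- is.na(ck)
        ok <- ok & !bad
        ck[bad] <- 1L
        sc <- sc + lodInt[cbind(ck, k)]
    }
    if (!any(ok)) return(NA_integer_)
    max(sc[ok])
}

#' Scan motif sets in windows centered on region peaks
#'
#' Both strands of a \code{window}-bp window centered on each region's
#' density peak are scored with every motif's log2-odds against a uniform
#' 0.25 background. The best hit's p-value comes from the exact null
#' score distribution (dynamic programming over the discretized PWM), and
#' its E-value is that p-value times the total number of windows scanned
#' in the run (all offsets, both strands, all regions). A region has a
#' hit for a motif set if any member motif's E-value is below
#' \code{eMax}.
#'
#' @param regions \code{GRanges} with a \code{peakPos} column (or width-1
#'   peaks).
#' @param motifSets named list; each element a named list/vector of PWMs
#'   (4 x width probability matrices) forming one TF's motif set.
#' @param genome named \code{DNAStringSet}.
#' @param window scan window in bp (odd; default 201).
#' @param eMax E-value threshold (default 10, strict inequality).
#' @param scale score discretization factor.
#' @return A list: \code{hitTable} (logical regions x sets matrix),
#'   \code{evalues} (regions x motifs), \code{nScanned}.
#' @export
scanMotifs <- function(regions, motifSets, genome, window = 201,
                       eMax = 10, scale = 1000) {
    stopifnot(window %% 2 == 1)
    half <- (window - 1L) %/% 2L
    pk <- if (!is.null(mcols(regions)$peakPos)) mcols(regions)$peakPos
          else start(regions)
    ## extract windows (truncated with a warning at chromosome ends)
    seqsF <- character(length(regions))
    for (i in seq_along(regions)) {
        chrom <- as.character(seqnames(regions)[i])
        L <- length(genome[[chrom]])
        a <- pk[i] - half; b <- pk[i] + half
        if (a < 1L || b > L) {
            warning("scan window truncated at chromosome end for region ",
                    i)
            a <- max(1L, a); b <- min(L, b)
        }
        seqsF[i] <- as.character(subseq(genome[[chrom]], a, b))
    }
    seqsR <- as.character(reverseComplement(DNAStringSet(seqsF)))
    codesF <- lapply(seqsF, .dnaCodes)
    codesR <- lapply(seqsR, .dnaCodes)

    allMotifs <- unlist(motifSets, recursive = FALSE)
    motifNames <- names(allMotifs)
    setOf <- rep(names(motifSets), lengths(motifSets))
    ev <- matrix(NA_real_, length(regions), length(allMotifs),
                 dimnames = list(names(regions), motifNames))
    nScanTotal <- 0
    for (mi in seq_along(allMotifs)) {
        lod <- .pwmIntScores(allMotifs[[mi]], scale)
        null <- .pwmNullDistribution(lod)
        w <- ncol(lod)
        nScan <- sum(vapply(codesF, function(cd)
            2L * max(0L, length(cd) - w + 1L), integer(1)))
        nScanTotal <- nScanTotal + nScan
        for (i in seq_along(regions)) {
            b1 <- .bestMotifScore(codesF[[i]], lod)
            b2 <- .bestMotifScore(codesR[[i]], lod)
            best <- suppressWarnings(max(b1, b2, na.rm = TRUE))
            if (!is.finite(best)) next
            ev[i, mi] <- .pwmPValue(null, best) * nScan
        }
    }
    hit <- matrix(FALSE, length(regions), length(motifSets),
                  dimnames = list(names(regions), names(motifSets)))
    for (s in names(motifSets)) {
        cols <- which(setOf == s)
        hit[, s] <- apply(ev[, cols, drop = FALSE], 1L,
                          function(e) any(!is.na(e) & e < eMax))
    }
    list(hitTable = hit, evalues = ev, nScanned = nScanTotal)
}

#' Collapse a pre-computed motif hit table by motif set
#'
#' The fidelity route for externally computed MAST hits: a tabular file
#' of per-region, per-motif E-values is collapsed with the same
#' any-member rule used by the built-in scanner.
#'
#' @param table data.frame with columns \code{region}, \code{motif},
#'   \code{evalue}.
#' @param setOf named character vector mapping motif name to set name.
#' @param regionIds region identifiers defining row order.
#' @param eMax E-value threshold (strict).
#' @return Logical regions x sets matrix.
#' @export
motifHitsFromTable <- function(table, setOf, regionIds, eMax = 10) {
    sets <- unique(unname(setOf))
    hit <- matrix(FALSE, length(regionIds), length(sets),
                  dimnames = list(regionIds, sets))
    ok <- table$evalue < eMax & table$region %in% regionIds &
        table$motif %in% names(setOf)
    for (r in which(ok))
        hit[table$region[r], setOf[[table$motif[r]]]] <- TRUE
    hit
}

#' Motif-table summaries
#'
#' Row sums give the number of distinct motif sets represented at each
#' region; column sums give the number of regions with at least one
#' motif from each set.
#'
#' @param hitTable logical regions x sets matrix.
#' @return List with \code{setsPerRegion} and \code{regionsPerSet}.
#' @export
motifSummaries <- function(hitTable) {
    list(setsPerRegion = rowSums(hitTable),
         regionsPerSet = colSums(hitTable))
}
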