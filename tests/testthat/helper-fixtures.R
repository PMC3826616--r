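suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(S4Vectors)
})

## Independent O(L * N) kernel-density oracle: literal double summation
## of the discrete smoothing formula.
bruteKde <- function(pos, counts, L, h) {
    denom <- sum(epanechnikovKernel((-h:h) / h))
    vapply(seq_len(L), function(i)
        sum(epanechnikovKernel((i - pos) / h) * counts), numeric(1)) /
        denom
}

## Minimal single-chromosome layout for fixtures.
tinyLayout <- function(L = 10000L, chrom = "chr1", ...) {
    sizes <- stats::setNames(as.integer(L), chrom)
    GenomeLayout(sizes, ...)
}

## HitTrack from bare positions on one chromosome.
tinyTrack <- function(pos, strand = rep("+", length(pos)),
                      counts = rep(1L, length(pos)), L = 10000L,
                      chrom = "chr1", layout = tinyLayout(L, chrom),
                      id = "s1", ...) {
    hitTrackFromPositions(rep(chrom, length(pos)), as.integer(pos),
                          strand, layout, SampleInfo(id, ...),
                          counts = counts)
}

denseProfile <- function(profile, chrom = "chr1") {
    as.numeric(profileValues(profile)[[chrom]])
}

## Hand-built SAM text with three alignments exercising the MAPQ /
## strand / 5'-end rules; returns the BAM path.
writeFixtureBam <- function(dir = tempfile()) {
    dir.create(dir, showWarnings = FALSE)
    sam <- file.path(dir, "fixture.sam")
    writeLines(c(
        "@HD\tVN:1.6\tSO:coordinate",
        "@SQ\tSN:chr1\tLN:10000",
        ## forward, MAPQ 30: hit at 1001 on +
        "r1\t0\tchr1\t1001\t30\t25M\t*\t0\t0\t*\t*",
        ## reverse, MAPQ 10 (posterior exactly 0.9): hit at 1025 on -
        "r2\t16\tchr1\t1001\t10\t25M\t*\t0\t0\t*\t*",
        ## forward, MAPQ 7 (posterior ~0.8): dropped at minPosterior 0.9
        "r3\t0\tchr1\t2001\t7\t25M\t*\t0\t0\t*\t*"), sam)
    Rsamtools::asBam(sam, file.path(dir, "fixture"),
                     overwrite = TRUE, indexDestination = TRUE)
}

## Welch two-sample t reference: the textbook formulas, written
## independently of stats::t.test.
welchReference <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    v1 <- sum((a - mean(a))^2) / (n1 - 1)
    v2 <- sum((b - mean(b))^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t), df)
    list(t = t, p = p, signedLogP = sign(mean(a) - mean(b)) * -log10(p))
}

## Simple probability PWM from a consensus string (weight on the
## consensus base, remainder spread evenly).
consensusPwm <- function(consensus, w = 0.97) {
    bases <- c("A", "C", "G", "T")
    m <- matrix((1 - w) / 3, 4, nchar(consensus),
                dimnames = list(bases, NULL))
    for (j in seq_len(nchar(consensus)))
        m[substr(consensus, j, j), j] <- w
    m
}
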