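## Deterministic strand pileups: identical unimodal shapes on the two
## strands, displaced by exactly 2 * s0.
displacedTrack <- function(center, s0, L = 10000L) {
    offs <- rep(-15:15, times = c(1:16, 15:1))   # triangular pileup
    fwdPos <- center - s0 + offs
    revPos <- center + s0 + offs
    tinyTrack(c(fwdPos, revPos),
              strand = rep(c("+", "-"), each = length(offs)), L = L)
}

test_that("a construction displaced by 2*s0 = 120 is estimated at s = 60", {
    tr <- displacedTrack(5000L, 60L)
    fwd <- smoothProfile(tr, 50L, "+")
    rev <- smoothProfile(tr, 50L, "-")
    regions <- GRanges("chr1", IRanges(4800L, 5200L))
    est <- estimateShift(fwd, rev, regions)
    expect_identical(strandShift(est), 60L)
    expect_gt(est@perRegion$maxCorr[1L], 0.999)
})

test_that("a degenerate one-point grid returns that shift regardless of data", {
    tr <- displacedTrack(3000L, 60L)
    est <- estimateShift(smoothProfile(tr, 50L, "+"),
                         smoothProfile(tr, 50L, "-"),
                         GRanges("chr1", IRanges(2800L, 3200L)),
                         minShift = 40L, maxShift = 40L)
    expect_identical(strandShift(est), 40L)
})

test_that("control shifts are the median of the ChIP shifts", {
    expect_identical(assignControlShift(c(60L, 70L, 80L)), 70L)
    expect_identical(assignControlShift(75L), 75L)
    expect_identical(assignControlShift(c(60L, 80L)), 70L)  # midpoint
    expect_error(assignControlShift(integer(0)), "no ChIP")
})

test_that("a flat background yields no preliminary regions", {
    L <- 5000L
    tr <- tinyTrack(seq_len(L), L = L)   # H is ~1 everywhere, 25x above it nowhere
    expect_error(preliminaryRegions(tr, tinyLayout(L)),
                 "insufficient enrichment")
})

test_that("preliminary regions are ranked by contained hit count and truncated", {
    L <- 60000L
    sites <- c(10000L, 20000L, 30000L, 40000L, 50000L)
    nReads <- c(40L, 80L, 120L, 160L, 200L)
    pos <- integer(0); str <- character(0)
    for (k in seq_along(sites)) {
        offs <- seq(-30L, 30L, length.out = nReads[k])
        pos <- c(pos, sites[k] + as.integer(offs))
        str <- c(str, rep(c("+", "-"), length.out = nReads[k]))
    }
    tr <- tinyTrack(pos, strand = str, L = L)
    prelim <- preliminaryRegions(tr, tinyLayout(L))
    counts <- mcols(prelim$regions)$hitCount
    expect_lte(length(prelim$regions), 5L)
    expect_true(all(diff(counts) <= 0))
    expect_equal(mcols(prelim$regions)$peakPos[1L], 50000L,
                 tolerance = 5)
    top3 <- preliminaryRegions(tr, tinyLayout(L), topN = 3L)
    expect_identical(length(top3$regions), 3L)
})

test_that("simulated fragments recover the shift near F/2", {
    layout <- tinyLayout(400000L)
    sites <- as.integer(seq(5000L, 395000L, length.out = 50))
    sim <- simulateChipseq(layout, sites, fragmentLength = 150,
                           readsPerSite = 100, backgroundRate = 0.001,
                           seed = 91)
    est <- estimateSampleShift(sim$tracks[[1L]], layout)
    expect_lte(abs(strandShift(est) - 75L), 7L)
})

test_that("strand exchange with coordinate mirroring leaves the estimate unchanged", {
    layout <- tinyLayout(200000L)
    sites <- as.integer(seq(5000L, 195000L, length.out = 25))
    sim <- simulateChipseq(layout, sites, fragmentLength = 120,
                           readsPerSite = 120, backgroundRate = 0.0005,
                           seed = 17)
    tr <- sim$tracks[[1L]]
    g <- hits(tr)
    L <- 200000L
    mirrored <- hitTrackFromPositions(
        as.character(seqnames(g)), L + 1L - start(g),
        ifelse(as.character(strand(g)) == "+", "-", "+"),
        layout, sampleInfo(tr), counts = mcols(g)$score)
    e1 <- estimateSampleShift(tr, layout)
    e2 <- estimateSampleShift(mirrored, layout)
    expect_identical(strandShift(e1), strandShift(e2))
    ## and the estimate is deterministic on identical input
    e3 <- estimateSampleShift(tr, layout)
    expect_identical(e1@perRegion, e3@perRegion)
    expect_identical(strandShift(e1), strandShift(e3))
})
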