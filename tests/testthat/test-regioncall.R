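profileFromValues <- function(vals, h = 100L) {
    new("DensityProfile",
        values = as(list(chr1 = Rle(vals)), "RleList"),
        strand = "*", bandwidth = h, shift = 0L)
}

test_that("region calling finds exactly the strict-threshold runs", {
    L <- 5000L
    layout <- tinyLayout(L)
    b <- 100 / L                       # totalReads = 100, egs = L
    vals <- rep(b, L)                  # uniform at background
    expect_length(callRegions(profileFromValues(vals), 100L, layout, 25),
                  0L)
    vals[1001:1100] <- 26 * b
    gr <- callRegions(profileFromValues(vals), 100L, layout, 25)
    expect_identical(start(gr), 1001L)
    expect_identical(end(gr), 1100L)
    ## a single below-threshold base splits a run in two
    vals[1050] <- b
    gr2 <- callRegions(profileFromValues(vals), 100L, layout, 25)
    expect_identical(start(gr2), c(1001L, 1051L))
    expect_identical(end(gr2), c(1049L, 1100L))
    expect_error(callRegions(profileFromValues(vals), 0L, layout, 25),
                 "positive")
})

test_that("the peak position is the leftmost argmax", {
    L <- 200L
    vals <- rep(0, L)
    vals[50:60] <- 1
    vals[c(53, 57)] <- 5                # tied maxima -> leftmost
    gr <- callRegions(profileFromValues(vals), 10L, tinyLayout(L), 2)
    expect_identical(mcols(gr)$peakPos, 53L)
})

test_that("the region set at fold 50 is nested within the fold-25 set", {
    set.seed(31)
    L <- 20000L
    vals <- as.numeric(stats::filter(rexp(L, 10), rep(1, 25),
                                     sides = 2))
    vals[is.na(vals)] <- 0
    p <- profileFromValues(vals)
    r25 <- callRegions(p, 1000L, tinyLayout(L), 25)
    r50 <- callRegions(p, 1000L, tinyLayout(L), 50)
    ov <- findOverlaps(r50, r25, type = "within")
    expect_identical(length(unique(S4Vectors::queryHits(ov))),
                     length(r50))
})

test_that("region kurtosis follows the weighted-moment formula", {
    ## discrete uniform over 101 positions: excess kurtosis ~ -1.2
    expect_equal(regionKurtosis(0:100), -6 * (101^2 + 1) / (5 * (101^2 - 1)),
                 tolerance = 1e-12)
    expect_lt(regionKurtosis(0:100), 0)
    ## zero positional variance is +Inf (fail convention)
    expect_identical(regionKurtosis(c(500L, 500L)), Inf)
    expect_identical(regionKurtosis(500L, 10L), Inf)
    ## a 1000-read stack with sparse scatter is strongly leptokurtic
    set.seed(32)
    pos <- c(200L, sample(1:400, 10L))
    cnt <- c(1000L, rep(1L, 10L))
    k <- regionKurtosis(pos, cnt)
    expect_gt(k, 50)
    ## brute-force oracle: expand the multiset and use literal moments
    expanded <- rep(pos, cnt)
    m <- mean(expanded)
    m2 <- mean((expanded - m)^2); m4 <- mean((expanded - m)^4)
    expect_equal(k, m4 / m2^2 - 3, tolerance = 1e-9)
    ## raw kurtosis differs by exactly +3
    expect_equal(regionKurtosis(pos, cnt, raw = TRUE), k + 3)
})

test_that("strand-correlation filtering matches a textbook Pearson", {
    L <- 300L
    set.seed(33)
    x <- rexp(50); y <- 0.6 * x + rexp(50, 5)
    fwd <- as(list(chr1 = Rle(c(rep(0, 100), x, rep(0, L - 150)))),
              "RleList")
    rev <- as(list(chr1 = Rle(c(rep(0, 100), y, rep(0, L - 150)))),
              "RleList")
    regions <- GRanges("chr1", IRanges(101L, 150L))
    ann <- annotateStrandCorrelation(regions, fwd, rev, minCorr = 0.3)
    sx <- x - mean(x); sy <- y - mean(y)
    rOracle <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
    expect_equal(mcols(ann)$strandCorr, rOracle, tolerance = 1e-12)
    ## identical shapes correlate at exactly 1
    ann1 <- annotateStrandCorrelation(regions, fwd, fwd)
    expect_equal(mcols(ann1)$strandCorr, 1)
    expect_true(mcols(ann1)$strandCorrPass)
    ## forward-only signal: undefined r, fail
    zero <- as(list(chr1 = Rle(rep(0, L))), "RleList")
    ann0 <- annotateStrandCorrelation(regions, fwd, zero)
    expect_true(is.na(mcols(ann0)$strandCorr))
    expect_false(mcols(ann0)$strandCorrPass)
})

test_that("structural filters enforce exact boundaries and are idempotent", {
    layout <- GenomeLayout(
        c(chr1 = 100000L, chrX = 100000L, chrM = 16571L),
        blacklist = GRanges("chr1", IRanges(5000L, 5999L)))
    regions <- GRanges(
        c("chr1", "chr1", "chr1", "chrX", "chrM", "chr1", "chr1"),
        IRanges(start = c(100L, 700L, 1500L, 100L, 100L, 4500L, 6000L),
                end   = c(600L, 1199L, 1999L, 400L, 300L, 4999L, 6300L)))
    ## widths: 501 (drop), 500 (keep), 500 (keep), chrX (drop),
    ## chrM (drop), ends 1 bp before blacklist (keep), starts at
    ## blacklist end boundary (keep: blacklist is 5000-5999)
    kept <- applyStructuralFilters(regions, layout)
    expect_identical(start(kept), c(700L, 1500L, 4500L, 6000L))
    ## sharing a single base with the blacklist drops a region
    touching <- GRanges("chr1", IRanges(5999L, 6100L))
    expect_length(applyStructuralFilters(touching, layout), 0L)
    expect_identical(applyStructuralFilters(kept, layout), kept)
})

test_that("hit counting respects shifts, boundaries, and conserves totals", {
    L <- 10000L
    layout <- tinyLayout(L)
    regions <- GRanges("chr1", IRanges(1001L, 1100L),
                       seqinfo = layout@seqinfo)
    ## forward hits shifted +10: 1090 -> 1100 (in), 1091 -> 1101 (out)
    tr <- tinyTrack(c(1090L, 1091L), L = L)
    se <- countHits(regions, list(tr), c(s1 = 10L))
    expect_identical(as.integer(assay(se)), 1L)
    expect_error(countHits(regions, list(tr), c(other = 10L)),
                 "no shift")
    ## brute-force membership oracle on a random 20-region fixture
    set.seed(34)
    starts <- sort(sample.int(L - 200L, 20L))
    regions <- GRanges("chr1", IRanges(starts, width = 50L),
                       seqinfo = layout@seqinfo)
    pos <- sample.int(L - 200L, 300L, replace = TRUE)
    str <- sample(c("+", "-"), 300L, replace = TRUE)
    tr <- tinyTrack(pos, strand = str, L = L)
    s <- 35L
    se <- countHits(regions, list(tr), c(s1 = s))
    shifted <- ifelse(str == "+", pos + s, pos - s)
    oracle <- vapply(seq_along(regions), function(i)
        sum(shifted >= start(regions)[i] & shifted <= end(regions)[i]),
        integer(1))
    expect_identical(as.integer(assay(se)), oracle)
    ## with every hit inside a region the column sum equals the total
    inside <- tinyTrack(rep(1050L, 7L), L = L)
    se2 <- countHits(GRanges("chr1", IRanges(1001L, 1100L),
                             seqinfo = layout@seqinfo),
                     list(inside), c(s1 = 0L))
    expect_identical(as.integer(sum(assay(se2))), totalHits(inside))
})
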