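test_that("Epanechnikov kernel matches its closed form", {
    expect_equal(epanechnikovKernel(0), 0.75)
    expect_equal(epanechnikovKernel(c(-1, 1)), c(0, 0))
    expect_equal(epanechnikovKernel(0.5), 0.5625)
    expect_equal(epanechnikovKernel(c(-2, 1.5)), c(0, 0))
})

test_that("a single hit smooths to the hand-computed triangle at h = 2", {
    tr <- tinyTrack(100L, L = 1000L)
    H <- denseProfile(smoothProfile(tr, 2L, "+"))
    ## weights (0.5625, 0.75, 0.5625) / 1.875 = (0.3, 0.4, 0.3)
    expect_equal(H[99:101], c(0.3, 0.4, 0.3))
    expect_equal(sum(H != 0), 3L)
})

test_that("constant counts give a constant density away from edges", {
    h <- 10L
    tr <- tinyTrack(seq_len(500L), counts = rep(5L, 500L), L = 500L)
    H <- denseProfile(smoothProfile(tr, h, "+"))
    expect_equal(H[(h + 1):(500 - h)], rep(5, 500 - 2 * h))
})

test_that("an empty strand yields an all-zero profile", {
    tr <- tinyTrack(50L, strand = "-", L = 200L)
    expect_equal(denseProfile(smoothProfile(tr, 5L, "+")), rep(0, 200))
})

test_that("production smoothing equals the brute-force double loop", {
    set.seed(21)
    for (rep in 1:5) {
        L <- 1000L
        n <- sample(5:40, 1L)
        pos <- sample.int(L, n, replace = TRUE)
        cnt <- sample.int(5L, n, replace = TRUE)
        h <- sample(2:60, 1L)
        tr <- tinyTrack(pos, counts = cnt, L = L)
        g <- hits(tr)
        H <- denseProfile(smoothProfile(tr, h, "+"))
        oracle <- bruteKde(start(g), mcols(g)$score, L, h)
        expect_lt(max(abs(H - oracle)), 1e-9)
    }
})

test_that("each interior hit contributes exactly unit mass", {
    set.seed(22)
    for (rep in 1:5) {
        L <- 2000L; h <- sample(5:100, 1L)
        pos <- sample((h + 1L):(L - h), 30L, replace = TRUE)
        cnt <- sample.int(4L, 30L, replace = TRUE)
        tr <- tinyTrack(pos, counts = cnt, L = L)
        H <- denseProfile(smoothProfile(tr, h, "+"))
        expect_equal(sum(H), sum(cnt), tolerance = 1e-12)
    }
})

test_that("smoothing is linear and translation-equivariant", {
    set.seed(23)
    L <- 1500L; h <- 25L
    posA <- sample(200:600, 15L); posB <- sample(700:1200, 20L)
    HA <- denseProfile(smoothProfile(tinyTrack(posA, L = L), h, "+"))
    HB <- denseProfile(smoothProfile(tinyTrack(posB, L = L), h, "+"))
    Hmerged <- denseProfile(
        smoothProfile(tinyTrack(c(posA, posB), L = L), h, "+"))
    expect_equal(Hmerged, HA + HB, tolerance = 1e-12)
    d <- 37L
    Hshift <- denseProfile(
        smoothProfile(tinyTrack(posA + d, L = L), h, "+"))
    expect_equal(Hshift[(d + 1):L], HA[1:(L - d)], tolerance = 1e-12)
})

test_that("combining strands translates +s / -s and sums", {
    L <- 400L
    fwd <- smoothProfile(tinyTrack(100L, L = L), 2L, "+")
    rev <- smoothProfile(tinyTrack(150L, strand = "-", L = L), 2L, "-")
    uni <- combineProfiles(fwd, rev, 25L)
    H <- denseProfile(uni)
    ## both point masses land at 125, doubled
    expect_equal(H[124:126], 2 * c(0.3, 0.4, 0.3))
    expect_equal(sum(H), 2, tolerance = 1e-12)
    ## s = 0 is the identity shift
    H0 <- denseProfile(combineProfiles(fwd, rev, 0L))
    expect_equal(H0, denseProfile(fwd) + denseProfile(rev))
    expect_error(combineProfiles(fwd, smoothProfile(
        tinyTrack(1L, strand = "-", L = L), 3L, "-"), 10L), "bandwidth")
})

test_that("pooling sample profiles equals smoothing the merged hits", {
    set.seed(24)
    L <- 2000L; h <- 30L; s <- 40L
    mk <- function(posF, posR)
        combineProfiles(
            smoothProfile(tinyTrack(posF, L = L), h, "+"),
            smoothProfile(tinyTrack(posR, strand = "-", L = L), h, "-"),
            s)
    pF1 <- sample(300:800, 5L); pR1 <- sample(300:800, 5L)
    pF2 <- sample(900:1500, 5L); pR2 <- sample(900:1500, 5L)
    pooled <- pooledProfile(list(mk(pF1, pR1), mk(pF2, pR2)))
    merged <- mk(c(pF1, pF2), c(pR1, pR2))
    expect_equal(denseProfile(pooled), denseProfile(merged),
                 tolerance = 1e-12)
    ## one profile pools to itself; empty list is an error
    one <- mk(pF1, pR1)
    expect_equal(denseProfile(pooledProfile(list(one))),
                 denseProfile(one))
    expect_error(pooledProfile(list()), "no profiles")
})
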