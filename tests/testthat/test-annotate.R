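peaksAt <- function(pos, chrom = "chr1")
    GRanges(chrom, IRanges(as.integer(pos), width = 1L),
            peakPos = as.integer(pos))

featsAt <- function(pos, strand = "*", chrom = "chr1")
    GRanges(chrom, IRanges(as.integer(pos), width = 1L), strand = strand)

test_that("nearest-feature matching honors the 500 bp bound and tie rule", {
    m <- matchNearest(peaksAt(1000), featsAt(1400))
    expect_true(m$matched)
    expect_identical(m$distance, 400L)
    ## 501 bp away is out of range
    expect_false(matchNearest(peaksAt(1000), featsAt(1501))$matched)
    ## nearest of several
    m2 <- matchNearest(peaksAt(1000), featsAt(c(700, 1200)))
    expect_identical(m2$featureIndex, 2L)
    expect_identical(m2$distance, 200L)
    ## exact tie resolves to the smaller coordinate
    m3 <- matchNearest(peaksAt(1000), featsAt(c(800, 1200)))
    expect_identical(m3$featureIndex, 1L)
    expect_identical(m3$distance, -200L)
    ## minus-strand feature: signed distance flips so negative means
    ## upstream on the feature's own strand
    m4 <- matchNearest(peaksAt(1000), featsAt(1400, strand = "-"))
    expect_identical(m4$distance, -400L)
})

test_that("matching equals an exhaustive distance scan on random fixtures", {
    set.seed(51)
    for (rep in 1:5) {
        pk <- sample.int(50000L, 40L)
        ft <- sort(sample.int(50000L, 25L))
        m <- matchNearest(peaksAt(pk), featsAt(ft))
        for (i in seq_along(pk)) {
            d <- abs(ft - pk[i])
            if (min(d) > 500) expect_false(m$matched[i])
            else {
                expect_true(m$matched[i])
                expect_identical(abs(m$distance[i]), min(d))
            }
        }
    }
})

test_that("consensus promoters require all three evidence classes", {
    pk <- peaksAt(c(1000, 5000, 9000))
    pol <- matchNearest(pk, featsAt(c(1100, 5100)))
    cage <- matchNearest(pk, featsAt(c(950, 9000)))
    tss <- matchNearest(pk, featsAt(c(1001, 5001, 9001)))
    expect_identical(consensusLabel(pol, cage, tss),
                     c(TRUE, FALSE, FALSE))
    ## consensus count never increases when the distance bound shrinks
    set.seed(52)
    pk <- peaksAt(sample.int(100000L, 50L))
    fa <- featsAt(sort(sample.int(100000L, 60L)))
    fb <- featsAt(sort(sample.int(100000L, 60L)))
    fc <- featsAt(sort(sample.int(100000L, 60L)))
    counts <- vapply(c(100, 250, 500, 1000), function(dmax)
        sum(consensusLabel(matchNearest(pk, fa, dmax),
                           matchNearest(pk, fb, dmax),
                           matchNearest(pk, fc, dmax))), integer(1))
    expect_true(all(diff(counts) >= 0))
})

test_that("sequence composition counts GC and CpG as defined", {
    genome <- Biostrings::DNAStringSet(c(chr1 = "GCGCATATNNNN"))
    regions <- GRanges("chr1", IRanges(c(1L, 5L, 9L), c(4L, 8L, 12L)))
    comp <- sequenceComposition(regions, genome)
    expect_equal(comp$gcFraction, c(1, 0, NA_real_))
    ## "GCGC" holds exactly one CG dimer over three dimer positions
    expect_equal(comp$cpgRate, c(1 / 3, 0, NA_real_))
    ## random 200-mer against a brute-force scan
    set.seed(53)
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
    genome2 <- Biostrings::DNAStringSet(c(chr1 = s))
    comp2 <- sequenceComposition(GRanges("chr1", IRanges(1L, 200L)),
                                 genome2)
    chars <- strsplit(s, "")[[1]]
    expect_equal(comp2$gcFraction, mean(chars %in% c("G", "C")))
    dimers <- paste0(chars[-200], chars[-1])
    expect_equal(comp2$cpgRate, sum(dimers == "CG") / 199)
})

test_that("constraint fraction uses strict inequality over scored bases", {
    mk <- function(starts, ends, scores)
        GRanges("chr1", IRanges(starts, ends), score = scores)
    region <- GRanges("chr1", IRanges(1L, 4L))
    scores <- mk(1:4, 1:4, c(3, 1, 2.5, 0))
    expect_equal(constraintFraction(region, scores), 0.5)
    ## exactly 2 everywhere: "greater than" is strict
    expect_equal(constraintFraction(region, mk(1L, 4L, 2)), 0)
    ## unscored positions leave the denominator; none scored is NA
    partial <- mk(c(1L, 3L), c(1L, 3L), c(5, 1))
    expect_equal(constraintFraction(region, partial), 0.5)
    expect_true(is.na(constraintFraction(
        GRanges("chr1", IRanges(50L, 60L)), scores)))
    ## mixed-coverage fixture against per-base brute force
    set.seed(54)
    sc <- mk(seq(1L, 200L, by = 4L), seq(2L, 200L, by = 4L),
             runif(50, 0, 4))
    reg <- GRanges("chr1", IRanges(37L, 150L))
    perBase <- unlist(lapply(seq_along(sc), function(i)
        stats::setNames(rep(mcols(sc)$score[i],
                            end(sc)[i] - start(sc)[i] + 1L),
                        start(sc)[i]:end(sc)[i])))
    covered <- as.integer(names(perBase))
    inReg <- covered >= 37 & covered <= 150
    expect_equal(constraintFraction(reg, sc),
                 mean(perBase[inReg] > 2))
})

test_that("gene-body counting pads 100 bp and respects strand checks", {
    L <- 10000L
    tr <- tinyTrack(c(899L, 900L, 1500L, 2100L, 2101L), L = L)
    gene <- GRanges("chr1", IRanges(1000L, 2000L), strand = "+")
    ## window [900, 2100]: 899 and 2101 fall just outside
    expect_identical(geneBodyCount(tr, gene), 3L)
    geneM <- GRanges("chr1", IRanges(1000L, 2000L), strand = "-")
    expect_identical(geneBodyCount(tr, geneM), 3L) # symmetric padding
    ## brute-force membership oracle
    set.seed(55)
    pos <- sample.int(5000L, 200L, replace = TRUE)
    tr2 <- tinyTrack(pos, L = L)
    genes <- GRanges("chr1", IRanges(c(500L, 2500L), c(1500L, 4000L)))
    cnt <- geneBodyCount(tr2, genes)
    expect_identical(cnt[1], sum(pos >= 400 & pos <= 1600))
    expect_identical(cnt[2], sum(pos >= 2400 & pos <= 4100))
})

test_that("the longest isoform is selected per gene", {
    tx <- GRanges("chr1", IRanges(c(100L, 100L, 900L), c(500L, 800L, 950L)),
                  gene_id = c("g1", "g1", "g2"))
    longest <- longestIsoform(tx)
    expect_identical(end(longest), c(800L, 950L))
})
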