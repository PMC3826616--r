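test_that("Pearson distances match the textbook definition", {
    set.seed(71)
    m <- matrix(rnorm(600), 100, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
    d <- pearsonDistance(m)
    expect_equal(diag(d), rep(0, 6), ignore_attr = TRUE)
    expect_equal(d, t(d))
    x <- m[, 1] - mean(m[, 1]); y <- m[, 2] - mean(m[, 2])
    rOracle <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    expect_equal(d[1, 2], 1 - rOracle, tolerance = 1e-12)
    ## identical and anti-correlated vectors hit the bounds
    m2 <- cbind(a = m[, 1], b = m[, 1], c = -m[, 1])
    d2 <- pearsonDistance(m2)
    expect_equal(d2["a", "b"], 0, tolerance = 1e-12)
    expect_equal(d2["a", "c"], 2, tolerance = 1e-12)
    m3 <- cbind(a = m[, 1], flat = rep(1, 100))
    expect_error(pearsonDistance(m3), "flat")
})

test_that("UPGMA merges at half the average distance and is ultrametric", {
    d <- matrix(c(0, 0.8, 0.8, 0), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    tree <- upgmaTree(d)
    expect_equal(sort(tree$edge.length), c(0.4, 0.4))
    ## an ultrametric 4x4 matrix is recovered exactly as path lengths
    labs <- c("a", "b", "c", "d")
    dm <- matrix(1, 4, 4, dimnames = list(labs, labs))
    dm[1, 2] <- dm[2, 1] <- 0.4
    dm[3, 4] <- dm[4, 3] <- 0.6
    diag(dm) <- 0
    tree4 <- upgmaTree(dm)
    coph <- ape::cophenetic.phylo(tree4)[labs, labs]
    expect_equal(coph, dm, tolerance = 1e-9)
    ## root-to-leaf depths equal (ultrametricity)
    depths <- ape::node.depth.edgelength(tree4)[1:4]
    expect_lt(max(depths) - min(depths), 1e-9)
    expect_error(upgmaTree(matrix(0, 1, 1)), "at least 2")
})

test_that("neighbor joining recovers additive trees exactly", {
    set.seed(72)
    for (n in c(5, 8)) {
        true <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
        true <- ape::unroot(true)
        dm <- ape::cophenetic.phylo(true)
        est <- njTree(dm)
        expect_equal(ape::dist.topo(ape::unroot(est), true)[1], 0,
                     ignore_attr = TRUE)
        cophEst <- ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)]
        expect_equal(cophEst, dm, tolerance = 1e-9)
    }
    ## n = 3: closed-form star branch lengths reproduce the distances
    labs <- c("a", "b", "c")
    d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
                 dimnames = list(labs, labs))
    star <- njTree(d3)
    coph3 <- ape::cophenetic.phylo(star)[labs, labs]
    expect_equal(coph3, d3, tolerance = 1e-12)
    expect_error(njTree(d3[1:2, 1:2]), "at least 3")
    ## ultrametric input: NJ and UPGMA agree on topology
    labs4 <- c("a", "b", "c", "d")
    dm4 <- matrix(1, 4, 4, dimnames = list(labs4, labs4))
    dm4[1, 2] <- dm4[2, 1] <- 0.4; dm4[3, 4] <- dm4[4, 3] <- 0.6
    diag(dm4) <- 0
    expect_equal(ape::dist.topo(ape::unroot(upgmaTree(dm4)),
                                ape::unroot(njTree(dm4)))[1], 0,
                 ignore_attr = TRUE)
})

test_that("replicate pooling averages per-target columns", {
    m <- cbind(a1 = c(1, 2), a2 = c(3, 4), b1 = c(5, 6))
    pooled <- poolReplicates(m, c("A", "A", "B"))
    expect_equal(pooled[, "A"], c(2, 3))
    expect_equal(pooled[, "B"], c(5, 6))
})

test_that("the motif-conditioned test matches the Welch reference", {
    set.seed(73)
    occ <- c(rnorm(10, 2, 0.5), rnorm(10, 1, 0.5))
    has <- rep(c(TRUE, FALSE), each = 10)
    res <- motifOccupancyTest(occ, has)
    ref <- welchReference(occ[has], occ[!has])
    expect_equal(res$t, ref$t, tolerance = 1e-10)
    expect_equal(res$signedLogP, ref$signedLogP, tolerance = 1e-10)
    expect_gt(res$signedLogP, 0)
    ## swapping labels flips the sign, same magnitude
    resSwap <- motifOccupancyTest(occ, !has)
    expect_equal(resSwap$signedLogP, -res$signedLogP, tolerance = 1e-12)
    ## identical groups: t = 0, signed log p = 0
    same <- c(1, 2, 3, 1, 2, 3)
    res0 <- motifOccupancyTest(same, rep(c(TRUE, FALSE), each = 3))
    expect_equal(res0$t, 0)
    expect_equal(res0$signedLogP, 0)
    ## undersized group is NA with a message
    expect_message(resNA <- motifOccupancyTest(occ, c(TRUE, rep(FALSE, 19))),
                   "fewer than 2")
    expect_true(is.na(resNA$p))
})

test_that("the Welch implementation agrees with the reference over many fixtures", {
    set.seed(74)
    for (i in 1:200) {
        n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
        a <- rnorm(n1, runif(1, -2, 2), runif(1, 0.2, 3))
        b <- rnorm(n2, runif(1, -2, 2), runif(1, 0.2, 3))
        res <- motifOccupancyTest(c(a, b),
                                  rep(c(TRUE, FALSE), c(n1, n2)))
        ref <- welchReference(a, b)
        expect_equal(res$signedLogP, ref$signedLogP, tolerance = 1e-10)
    }
})

test_that("interaction splitting partitions pairs and excludes replicates", {
    set.seed(75)
    latent <- rnorm(200)
    occ <- cbind(A1 = latent + rnorm(200, sd = 0.5),
                 B1 = latent + rnorm(200, sd = 0.5),
                 C1 = rnorm(200), D1 = rnorm(200),
                 A2 = latent + rnorm(200, sd = 0.5))
    targets <- c("A", "B", "C", "D", "A")
    pairs <- data.frame(x = "A", y = "B")
    res <- interactionCorrelationSplit(occ, targets, pairs)
    ## C(5,2) = 10 pairs minus the A-A replicate pair
    expect_identical(length(res$binding) + length(res$nonbinding), 9L)
    expect_identical(length(res$binding), 2L)   # A1-B1 and A2-B1
    expect_gt(res$meanDifference, 0)
    ## replicate-only input has no usable pairs
    expect_error(interactionCorrelationSplit(
        occ[, c("A1", "A2")], c("A", "A"), pairs), "binding")
})
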