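#' @include reads-io.R
NULL

.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    withr::with_seed(as.integer(seed), expr)
}

#' Simulate strand-asymmetric multi-sample ChIP-seq hit tracks
#'
#' Plants point binding sites and generates, per sample and site, a
#' Poisson number of reads; each read lands on a uniformly chosen strand
#' with its 5' start at site -F/2 (forward) or site +F/2 (reverse) plus
#' rounded normal jitter (sd F/10 by default), emulating sequencing from
#' the two ends of sheared fragments of length F. Uniform background
#' reads are added on every chromosome; negative controls are
#' background-only. The expected per-strand shift is F/2.
#'
#' @param layout a \linkS4class{GenomeLayout}.
#' @param sites site positions: integer vector (placed on \code{chrom})
#'   or data.frame with \code{chrom} and \code{pos}.
#' @param fragmentLength sheared fragment length F in bp (>= 2).
#' @param readsPerSite expected reads per site per sample.
#' @param backgroundRate background reads per bp per sample.
#' @param nSamples number of ChIP samples.
#' @param nControls number of background-only control samples.
#' @param seed RNG seed; identical seeds give identical tracks.
#' @param intensities optional sites x samples intensity multipliers
#'   (default 1).
#' @param jitterSd sd of the positional jitter (default F/10).
#' @param chrom chromosome for numeric \code{sites}.
#' @return List with \code{tracks} (ChIP then control
#'   \linkS4class{HitTrack}s) and \code{truth} (sites, fragment length,
#'   expected shift F/2, rates, seed).
#' @export
simulateChipseq <- function(layout, sites, fragmentLength,
                            readsPerSite = 100, backgroundRate = 0.001,
                            nSamples = 1, nControls = 0, seed = 1,
                            intensities = NULL,
                            jitterSd = fragmentLength / 10,
                            chrom = NULL) {
    stopifnot(fragmentLength >= 2)
    sl <- seqlengths(layout@seqinfo)
    if (is.null(chrom)) chrom <- names(sl)[1L]
    siteTab <- if (is.data.frame(sites)) sites
               else data.frame(chrom = chrom, pos = as.integer(sites))
    lim <- sl[siteTab$chrom]
    if (any(siteTab$pos <= fragmentLength |
            siteTab$pos > lim - fragmentLength))
        stop("site within one fragment length of a chromosome end")
    nSites <- nrow(siteTab)
    if (is.null(intensities))
        intensities <- matrix(1, nSites, nSamples)
    half <- fragmentLength / 2

    .withSeed(seed, {
        mkBackground <- function() {
            ch <- character(0); ps <- integer(0); st <- character(0)
            for (cn in names(sl)) {
                nbg <- stats::rpois(1L, backgroundRate * sl[[cn]])
                if (nbg == 0L) next
                ch <- c(ch, rep(cn, nbg))
                ps <- c(ps, sample.int(sl[[cn]], nbg, replace = TRUE))
                st <- c(st, sample(c("+", "-"), nbg, replace = TRUE))
            }
            list(chrom = ch, pos = ps, strand = st)
        }
        tracks <- vector("list", nSamples + nControls)
        for (s in seq_len(nSamples)) {
            ch <- character(0); ps <- integer(0); st <- character(0)
            for (k in seq_len(nSites)) {
                nr <- stats::rpois(1L, readsPerSite * intensities[k, s])
                if (nr == 0L) next
                fwd <- stats::runif(nr) < 0.5
                ctr <- ifelse(fwd, siteTab$pos[k] - half,
                              siteTab$pos[k] + half)
                p <- as.integer(round(ctr + stats::rnorm(nr,
                                                         sd = jitterSd)))
                ok <- p >= 1L & p <= sl[[siteTab$chrom[k]]]
                ch <- c(ch, rep(siteTab$chrom[k], sum(ok)))
                ps <- c(ps, p[ok])
                st <- c(st, ifelse(fwd[ok], "+", "-"))
            }
            bg <- mkBackground()
            info <- SampleInfo(sprintf("chip_%02d", s), target = "simTF",
                               cellType = "sim", lab = "sim",
                               replicate = s)
            tracks[[s]] <- hitTrackFromPositions(
                c(ch, bg$chrom), c(ps, bg$pos), c(st, bg$strand),
                layout, info)
        }
        for (s in seq_len(nControls)) {
            bg <- mkBackground()
            info <- SampleInfo(sprintf("input_%02d", s),
                               target = "input", cellType = "sim",
                               lab = "sim", replicate = s,
                               isControl = TRUE)
            tracks[[nSamples + s]] <- hitTrackFromPositions(
                bg$chrom, bg$pos, bg$strand, layout, info)
        }
        list(tracks = tracks,
             truth = list(sites = siteTab,
                          intensities = intensities,
                          fragmentLength = fragmentLength,
                          expectedShift = fragmentLength / 2,
                          readsPerSite = readsPerSite,
                          backgroundRate = backgroundRate,
                          jitterSd = jitterSd, seed = seed))
    })
}

#' Simulate a negative-binomial count experiment
#'
#' Region means are log-uniform over \code{meanRange}; sample depths are
#' log-uniform size factors over \code{sizeFactorRange} (or given
#' explicitly); counts are NB(mu = mean * factor, dispersion alpha), or
#' Poisson when \code{dispersion = 0}.
#'
#' @param nRegions,nSamples matrix dimensions.
#' @param meanRange range of region means.
#' @param dispersion NB dispersion alpha (>= 0).
#' @param sizeFactorRange range for random size factors.
#' @param sizeFactors optional explicit per-sample factors.
#' @param classIds per-sample normalization classes (default: all one
#'   class).
#' @param seed RNG seed.
#' @return List with a \code{SummarizedExperiment} (\code{counts} assay,
#'   sample metadata) and \code{truth} (mu, factors, dispersion).
#' @export
simulateNBCounts <- function(nRegions, nSamples, meanRange = c(10, 1000),
                             dispersion = 0.1,
                             sizeFactorRange = c(0.5, 2),
                             sizeFactors = NULL,
                             classIds = rep("class1", nSamples),
                             seed = 1) {
    stopifnot(dispersion >= 0)
    .withSeed(seed, {
        mu <- exp(stats::runif(nRegions, log(meanRange[1L]),
                               log(meanRange[2L])))
        f <- if (is.null(sizeFactors))
            exp(stats::runif(nSamples, log(sizeFactorRange[1L]),
                             log(sizeFactorRange[2L])))
        else sizeFactors
        mat <- matrix(0L, nRegions, nSamples)
        for (s in seq_len(nSamples)) {
            m <- mu * f[s]
            mat[, s] <- if (dispersion > 0)
                stats::rnbinom(nRegions, mu = m, size = 1 / dispersion)
            else stats::rpois(nRegions, m)
        }
        ids <- sprintf("s%02d", seq_len(nSamples))
        colnames(mat) <- ids
        rownames(mat) <- sprintf("region_%05d", seq_len(nRegions))
        samples <- lapply(seq_len(nSamples), function(s)
            SampleInfo(ids[s], target = "simTF", cellType = "sim",
                       lab = classIds[s], replicate = s,
                       classId = classIds[s]))
        se <- SummarizedExperiment(
            assays = list(counts = mat),
            colData = .sampleInfoFrame(samples))
        list(se = se, truth = list(mu = mu, sizeFactors = f,
                                   dispersion = dispersion, seed = seed))
    })
}

#' Simulate latent-factor occupancy and regulation readouts
#'
#' A rank-k latent factor matrix (factor j has standard deviation
#' decreasing linearly from 3 to 1) generates both the TF occupancy
#' block X_TF = Z W + noise and the regulation readouts Y = Z B + noise;
#' the control block X_input is independent noise. This emulates the
#' regime where TF occupancy carries the regulatory signal and input
#' does not.
#'
#' @param nRegions,nTfs,nControls,nResponses dimensions.
#' @param rank number of latent factors k (<= nTfs).
#' @param noiseSd additive Gaussian noise sd on X_TF and Y.
#' @param seed RNG seed.
#' @return List with \code{xTF}, \code{xInput}, \code{Y} and
#'   \code{truth} (B, W, rank, factor sds).
#' @export
simulateRegulation <- function(nRegions = 200, nTfs = 20, nControls = 3,
                               rank = 3, noiseSd = 0.1, nResponses = 6,
                               seed = 1) {
    stopifnot(rank <= nTfs)
    .withSeed(seed, {
        sds <- seq(3, 1, length.out = rank)
        Z <- sapply(sds, function(s) stats::rnorm(nRegions, sd = s))
        Z <- matrix(Z, nRegions, rank)
        W <- matrix(stats::rnorm(rank * nTfs), rank, nTfs)
        B <- matrix(stats::rnorm(rank * nResponses), rank, nResponses)
        xTF <- Z %*% W +
            matrix(stats::rnorm(nRegions * nTfs, sd = noiseSd),
                   nRegions, nTfs)
        Y <- Z %*% B +
            matrix(stats::rnorm(nRegions * nResponses, sd = noiseSd),
                   nRegions, nResponses)
        xInput <- matrix(stats::rnorm(nRegions * nControls), nRegions,
                         nControls)
        colnames(xTF) <- sprintf("tf%02d", seq_len(nTfs))
        colnames(xInput) <- sprintf("input%d", seq_len(nControls))
        colnames(Y) <- sprintf("response%d", seq_len(nResponses))
        list(xTF = xTF, xInput = xInput, Y = Y,
             truth = list(B = B, W = W, rank = rank, factorSd = sds,
                          noiseSd = noiseSd, seed = seed))
    })
}
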