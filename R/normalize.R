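#' @include region-calling.R
NULL

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors: the median over regions of the
#' sample's count divided by the region's geometric mean across samples,
#' computed over regions with all-positive counts.
#'
#' @param mat integer count matrix (regions x samples).
#' @return Positive numeric vector of per-sample factors.
#' @export
sizeFactorsFromCounts <- function(mat) {
    ok <- rowSums(mat > 0) == ncol(mat)
    if (sum(ok) < 2L)
        stop("fewer than 2 regions with positive counts in every sample;",
             " consider adding a pseudocount")
    lg <- log(mat[ok, , drop = FALSE])
    geo <- rowMeans(lg)
    exp(apply(lg - geo, 2L, stats::median))
}

#' Fit the dispersion-mean relationship
#'
#' Within every normalization class holding at least two samples, the
#' per-region mean q and variance w of size-factor-normalized counts are
#' estimated; the points from all classes are pooled into one
#' analysis-wide set and the variance trend is fitted by a fixed-span
#' local linear regression of log variance on log mean (the log of a
#' sample variance is debiased analytically before fitting). Only the
#' fitted relationship is kept: the returned object maps a normalized
#' mean q to a fitted dispersion via alpha(q) = (w(q) - q * cbar) / q^2,
#' floored at a small positive value, where cbar is the mean inverse size
#' factor (the Poisson sampling term).
#'
#' @param mat count matrix (regions x samples).
#' @param factors per-sample size factors.
#' @param classes per-sample class ids; replicates from different labs
#'   belong to separate classes.
#' @param span loess span for the local fit (default 0.3).
#' @param method \code{"local"} for the fitted trend, \code{"scalar"} for
#'   a single pooled dispersion value.
#' @param alphaFloor lower bound on the fitted dispersion.
#' @return A \code{DispersionFit} object (list with the \code{alpha}
#'   function, the pooled points, and the method).
#' @export
fitDispersionTrend <- function(mat, factors, classes, span = 0.3,
                               method = c("local", "scalar"),
                               alphaFloor = 1e-8) {
    method <- match.arg(method)
    tab <- table(classes)
    useClasses <- names(tab)[tab >= 2L]
    if (length(useClasses) == 0L)
        stop("all classes are singletons: no replicates to estimate",
             " dispersion from")
    norm <- sweep(mat, 2L, factors, "/")
    pts <- list()
    for (cl in useClasses) {
        cols <- which(classes == cl)
        sub <- norm[, cols, drop = FALSE]
        q <- rowMeans(sub)
        w <- apply(sub, 1L, stats::var)
        m <- length(cols)
        keep <- q > 0
        ## exact-zero variances (identical replicates) carry real
        ## information about a near-zero dispersion: floor, don't drop
        pts[[cl]] <- data.frame(q = q[keep], w = pmax(w[keep], 1e-8),
                                m = m, zc = mean(1 / factors[cols]))
    }
    pts <- do.call(rbind, pts)
    if (nrow(pts) < 10L)
        stop("too few informative regions to fit a dispersion trend")
    ## debias log of a sample variance: E log(s^2) - log(sigma^2)
    ##   = digamma((m-1)/2) - log((m-1)/2) under normal-theory scaling
    bias <- digamma((pts$m - 1) / 2) - log((pts$m - 1) / 2)
    logw <- log(pts$w) - bias
    logq <- log(pts$q)
    cbar <- mean(pts$zc)
    qRange <- range(pts$q)
    if (method == "local") {
        fit <- stats::loess(logw ~ logq, span = span, degree = 1,
                            family = "gaussian",
                            control = stats::loess.control(surface =
                                                           "direct"))
        alphaFun <- function(q) {
            qc <- pmin(pmax(q, qRange[1L]), qRange[2L])
            wq <- exp(stats::predict(fit, data.frame(logq = log(qc))))
            pmax((wq - qc * cbar) / qc^2, alphaFloor)
        }
    } else {
        rawAlpha <- (pts$w - pts$q * pts$zc) / pts$q^2
        aScalar <- max(stats::median(rawAlpha), alphaFloor)
        alphaFun <- function(q) rep(aScalar, length(q))
    }
    structure(list(alpha = alphaFun, points = pts, method = method,
                   cbar = cbar, qRange = qRange),
              class = "DispersionFit")
}

#' Variance-stabilizing transformation
#'
#' Maps normalized counts q through tau(q) = integral from 0 to q of
#' dv / sqrt(w(v)) with the fitted variance function
#' w(v) = v + alpha(v) v^2, so that the transformed values have
#' approximately mean-independent variance. The integral is evaluated on
#' the substitution v = t^2 (which removes the square-root singularity at
#' zero: tau(q) = integral of 2 dt / sqrt(1 + alpha(t^2) t^2) up to
#' sqrt(q)) by cumulative trapezoid on a fine grid, then interpolated
#' with a monotone spline. tau(0) = 0; tau is strictly increasing; in the
#' Poisson limit alpha -> 0 it approaches 2 sqrt(q).
#'
#' @param mat count matrix (regions x samples).
#' @param factors per-sample size factors.
#' @param dispersionFit a \code{DispersionFit} from
#'   \code{\link{fitDispersionTrend}}.
#' @param gridPoints resolution of the integration grid.
#' @return Numeric matrix of occupancy scores, same shape and dimnames.
#' @export
vstTransform <- function(mat, factors, dispersionFit, gridPoints = 4096L) {
    norm <- sweep(mat, 2L, factors, "/")
    qmax <- max(norm, 1)
    tg <- seq(0, sqrt(qmax) * 1.001, length.out = gridPoints + 1L)
    a <- dispersionFit$alpha(tg^2)
    if (any(1 + a * tg^2 <= 0)) stop("negative fitted variance")
    g <- 2 / sqrt(1 + a * tg^2)
    dt <- diff(tg)
    tau <- c(0, cumsum((g[-1L] + g[-length(g)]) / 2 * dt))
    f <- stats::splinefun(tg^2, tau, method = "hyman")
    out <- matrix(f(norm), nrow = nrow(mat), dimnames = dimnames(mat))
    out
}

#' Normalize a count experiment to continuous occupancy scores
#'
#' End-to-end normalization of a regions x samples count experiment:
#' median-of-ratios size factors, pooled dispersion-mean fit over the
#' replicate classes in \code{colData(se)$classId}, and the
#' variance-stabilizing transformation. Adds an \code{occupancy} assay, a
#' \code{sizeFactor} column, and records the dispersion fit in the
#' metadata.
#'
#' @param se a \code{SummarizedExperiment} with a \code{counts} assay and
#'   \code{classId} in its \code{colData}.
#' @param span,method,alphaFloor passed to
#'   \code{\link{fitDispersionTrend}}.
#' @return The augmented \code{SummarizedExperiment}.
#' @export
normalizeOccupancy <- function(se, span = 0.3, method = "local",
                               alphaFloor = 1e-8) {
    mat <- assay(se, "counts")
    factors <- sizeFactorsFromCounts(mat)
    fit <- fitDispersionTrend(mat, factors, colData(se)$classId,
                              span = span, method = method,
                              alphaFloor = alphaFloor)
    occ <- vstTransform(mat, factors, fit)
    SummarizedExperiment::assays(se)$occupancy <- occ
    colData(se)$sizeFactor <- factors
    metadata(se)$dispersionFit <- fit
    se
}
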