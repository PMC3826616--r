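#' @include normalize.R
NULL

#' Pearson distance matrix between samples
#'
#' d(a, b) = 1 - r where r is the Pearson correlation of the two
#' samples' occupancy vectors over all regions. Entries lie in [0, 2].
#'
#' @param occ occupancy matrix (regions x samples) with column names.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pearsonDistance <- function(occ) {
    if (nrow(occ) < 2L) stop("need at least 2 regions")
    sds <- apply(occ, 2L, stats::sd)
    if (any(sds == 0))
        stop("zero-variance sample(s): ",
             paste(colnames(occ)[sds == 0], collapse = ", "))
    d <- 1 - stats::cor(occ)
    diag(d) <- 0
    d
}

#' UPGMA tree from a distance matrix
#'
#' Rooted ultrametric tree by average-linkage hierarchical clustering:
#' merge heights are half the average inter-cluster distance, so
#' root-to-leaf path lengths are equal. Ties between minimal pairs break
#' deterministically by index order.
#'
#' @param d symmetric distance matrix with labeled rows/columns.
#' @return An \code{ape} \code{phylo} tree (rooted).
#' @export
upgmaTree <- function(d) {
    if (nrow(as.matrix(d)) < 2L) stop("need at least 2 samples")
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    ape::as.phylo(hc)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard branch-length formulas
#' (via \code{ape::nj}); the result is unrooted and, for an additive
#' input matrix, recovers the generating tree exactly.
#'
#' @param d symmetric distance matrix, n >= 3 samples.
#' @return An unrooted \code{phylo} tree, serializable as newick with
#'   \code{ape::write.tree}.
#' @export
njTree <- function(d) {
    if (nrow(as.matrix(d)) < 3L) stop("need at least 3 samples")
    ape::nj(stats::as.dist(d))
}

#' Pool replicate occupancy columns by target
#'
#' Per-TF occupancy is the mean of the variance-stabilized replicate
#' columns sharing that target.
#'
#' @param occ occupancy matrix (regions x samples).
#' @param targets character vector of targets, one per column.
#' @return Matrix (regions x unique targets).
#' @export
poolReplicates <- function(occ, targets) {
    stopifnot(length(targets) == ncol(occ))
    out <- vapply(unique(targets), function(tf)
        rowMeans(occ[, targets == tf, drop = FALSE]),
        numeric(nrow(occ)))
    rownames(out) <- rownames(occ)
    out
}

#' Motif-conditioned occupancy test
#'
#' Two-sample t-test (Welch by default) for the difference in a TF's
#' pooled occupancy between consensus promoters carrying the motif set
#' and those without it. The statistic reported is the signed log10
#' p-value: positive when occupancy is higher at motif-bearing promoters.
#'
#' @param occ numeric occupancy vector over regions (replicates pooled).
#' @param hasMotif logical vector, same length.
#' @param varEqual \code{FALSE} for Welch (default), \code{TRUE} for the
#'   pooled-variance Student test.
#' @return List with \code{t}, \code{p}, \code{signedLogP}, \code{nWith},
#'   \code{nWithout}; \code{NA}s (with a message) if either group has
#'   fewer than 2 members.
#' @export
motifOccupancyTest <- function(occ, hasMotif, varEqual = FALSE) {
    a <- occ[hasMotif]; b <- occ[!hasMotif]
    if (length(a) < 2L || length(b) < 2L) {
        message("motif test skipped: a group has fewer than 2 promoters")
        return(list(t = NA_real_, p = NA_real_, signedLogP = NA_real_,
                    nWith = length(a), nWithout = length(b)))
    }
    tt <- stats::t.test(a, b, var.equal = varEqual)
    sgn <- sign(mean(a) - mean(b))
    list(t = unname(tt$statistic), p = tt$p.value,
         signedLogP = sgn * -log10(tt$p.value),
         nWith = length(a), nWithout = length(b))
}

#' All TF x motif-set occupancy tests
#'
#' @param tfOcc pooled occupancy matrix (consensus promoters x TFs).
#' @param hitTable logical matrix (same promoters x motif sets).
#' @param varEqual see \code{\link{motifOccupancyTest}}.
#' @return data.frame with one row per TF/set combination.
#' @export
motifOccupancyTests <- function(tfOcc, hitTable, varEqual = FALSE) {
    stopifnot(nrow(tfOcc) == nrow(hitTable))
    grid <- expand.grid(tf = colnames(tfOcc), set = colnames(hitTable),
                        stringsAsFactors = FALSE)
    res <- lapply(seq_len(nrow(grid)), function(i)
        suppressMessages(motifOccupancyTest(tfOcc[, grid$tf[i]],
                                            hitTable[, grid$set[i]],
                                            varEqual)))
    cbind(grid, do.call(rbind, lapply(res, as.data.frame)))
}

#' Split sample-pair correlations by known TF-TF interaction
#'
#' Pearson correlations of all sample pairs' occupancy profiles are
#' partitioned into pairs whose targets are a listed (physically
#' binding) TF pair versus pairs that are not; replicate pairs of the
#' same TF are excluded entirely.
#'
#' @param occ occupancy matrix (regions x samples).
#' @param targets per-column TF names.
#' @param pairs data.frame (or 2-column matrix) of interacting TF name
#'   pairs, unordered.
#' @return List with \code{binding}, \code{nonbinding} correlation
#'   vectors and \code{meanDifference} (binding minus non-binding).
#' @export
interactionCorrelationSplit <- function(occ, targets, pairs) {
    stopifnot(length(targets) == ncol(occ))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    bindingKeys <- unique(key(as.character(pairs[[1L]]),
                              as.character(pairs[[2L]])))
    cm <- stats::cor(occ)
    n <- ncol(occ)
    binding <- numeric(0); nonbinding <- numeric(0)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (targets[i] == targets[j]) next
        if (key(targets[i], targets[j]) %in% bindingKeys)
            binding <- c(binding, cm[i, j])
        else nonbinding <- c(nonbinding, cm[i, j])
    }
    if (length(binding) == 0L)
        stop("no usable sample pairs in the binding class")
    if (length(nonbinding) == 0L)
        stop("no usable sample pairs in the non-binding class")
    list(binding = binding, nonbinding = nonbinding,
         meanDifference = mean(binding) - mean(nonbinding))
}
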