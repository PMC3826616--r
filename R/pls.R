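#' @include AllClasses.R
NULL

## SIMPLS on already centered (and optionally scaled) X, Y. Returns
## projection weights R (x %*% R = scores), loadings P, Q, scores TT and
## the coefficient array B (p x q x A), all on the internal scale.
.simpls <- function(X, Y, A) {
    n <- nrow(X); p <- ncol(X); q <- ncol(Y)
    R <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, q, A)
    TT <- matrix(0, n, A); V <- matrix(0, p, A)
    S <- crossprod(X, Y)
    B <- array(0, dim = c(p, q, A))
    for (a in seq_len(A)) {
        r <- svd(S, nu = 1L, nv = 0L)$u[, 1L]
        t <- X %*% r
        nt <- sqrt(sum(t^2))
        if (nt < 1e-12) {                 # rank exhausted
            A <- a - 1L
            break
        }
        t <- t / nt; r <- r / nt
        pvec <- crossprod(X, t)
        qvec <- crossprod(Y, t)
        v <- pvec
        if (a > 1L) {
            Vp <- V[, seq_len(a - 1L), drop = FALSE]
            v <- v - Vp %*% crossprod(Vp, pvec)
        }
        v <- v / sqrt(sum(v^2))
        S <- S - v %*% crossprod(v, S)
        R[, a] <- r; P[, a] <- pvec; Q[, a] <- qvec
        TT[, a] <- t; V[, a] <- v
        B[, , a] <- R[, seq_len(a), drop = FALSE] %*%
            t(Q[, seq_len(a), drop = FALSE])
    }
    if (A < 1L) stop("predictor block has no usable variance")
    list(R = R[, seq_len(A), drop = FALSE],
         P = P[, seq_len(A), drop = FALSE],
         Q = Q[, seq_len(A), drop = FALSE],
         scores = TT[, seq_len(A), drop = FALSE],
         B = B[, , seq_len(A), drop = FALSE], A = A)
}

.scaleBlock <- function(M, autoscale) {
    ctr <- colMeans(M)
    scl <- if (autoscale) apply(M, 2L, stats::sd) else rep(1, ncol(M))
    scl[scl == 0] <- 1
    list(M = sweep(sweep(M, 2L, ctr), 2L, scl, "/"), center = ctr,
         scale = scl)
}

#' Fit a PLS regulation model with LOO component selection
#'
#' Two-block partial least-squares regression (SIMPLS) of a
#' gene-regulation readout matrix Y on an occupancy predictor matrix X,
#' both column-centered and (by default) autoscaled to unit variance.
#' The latent-variable count is chosen by leave-one-out cross-validation:
#' RMSEP, averaged over response columns on the original response scale,
#' is evaluated at each component count, and the model keeps the first
#' latent variable plus every subsequent one that lowers the average
#' RMSEP by at least \code{rmsepDelta} (applied greedily in component
#' order). Per-response LOO R-squared at the selected count is reported
#' as 1 - PRESS/TSS, with TSS taken about the overall column mean; a
#' constant response column is assigned R-squared 0.
#'
#' @param X numeric predictor matrix (rows = regions); zero-variance
#'   columns are dropped with a warning.
#' @param Y numeric response matrix (or vector).
#' @param variant label stored on the model: \code{"full"} (controls +
#'   TF occupancy) or \code{"null"} (input/controls only).
#' @param autoscale scale columns to unit variance (default TRUE).
#' @param ncomp fixed component count, skipping the RMSEP rule.
#' @param rmsepDelta minimum average-RMSEP decrease to keep a component
#'   (default 0.01).
#' @param maxComp cap on candidate components (default
#'   \code{min(n - 2, p, 15)}).
#' @return A \linkS4class{PLSModel}.
#' @export
plsFit <- function(X, Y, variant = c("full", "null"), autoscale = TRUE,
                   ncomp = NULL, rmsepDelta = 0.01, maxComp = NULL) {
    variant <- match.arg(variant)
    X <- as.matrix(X); Y <- as.matrix(Y)
    if (is.null(colnames(Y)))
        colnames(Y) <- paste0("y", seq_len(ncol(Y)))
    n <- nrow(X)
    if (n < 3L) stop("need at least 3 complete rows")
    keep <- apply(X, 2L, stats::sd) > 0
    if (!all(keep)) {
        warning(sum(!keep), " zero-variance predictor column(s) dropped")
        X <- X[, keep, drop = FALSE]
    }
    if (ncol(X) == 0L) stop("no predictor columns with variance")
    A <- if (is.null(maxComp)) min(n - 2L, ncol(X), 15L)
         else min(maxComp, n - 2L, ncol(X))
    A <- max(A, 1L)

    ## literal leave-one-out: refit on each n-1 subset, predict the
    ## held-out row at every component count
    pred <- array(NA_real_, dim = c(n, ncol(Y), A))
    for (i in seq_len(n)) {
        xi <- X[-i, , drop = FALSE]; yi <- Y[-i, , drop = FALSE]
        sx <- .scaleBlock(xi, autoscale); sy <- .scaleBlock(yi, autoscale)
        fit <- .simpls(sx$M, sy$M, A)
        x0 <- (X[i, ] - sx$center) / sx$scale
        for (a in seq_len(fit$A)) {
            yhat <- drop(x0 %*% fit$B[, , a])
            pred[i, , a] <- yhat * sy$scale + sy$center
        }
        if (fit$A < A)
            for (a in seq((fit$A + 1L), A)) pred[i, , a] <- pred[i, , fit$A]
    }
    rmsep <- vapply(seq_len(A), function(a)
        mean(sqrt(colMeans((Y - pred[, , a, drop = FALSE][, , 1L])^2))),
        numeric(1))

    if (is.null(ncomp)) {
        ncomp <- 1L
        while (ncomp < A && rmsep[ncomp + 1L] <= rmsep[ncomp] -
               rmsepDelta)
            ncomp <- ncomp + 1L
    }
    ncomp <- min(ncomp, A)

    press <- colSums((Y - pred[, , ncomp, drop = FALSE][, , 1L])^2)
    tss <- colSums(sweep(Y, 2L, colMeans(Y))^2)
    cvR2 <- ifelse(tss > 0, 1 - press / tss, 0)
    names(cvR2) <- colnames(Y)

    sx <- .scaleBlock(X, autoscale); sy <- .scaleBlock(Y, autoscale)
    fit <- .simpls(sx$M, sy$M, max(ncomp, 1L))
    new("PLSModel", weights = fit$R, xLoadings = fit$P,
        yLoadings = fit$Q, scores = fit$scores,
        coefficients = fit$B, xCenter = sx$center, xScale = sx$scale,
        yCenter = sy$center, yScale = sy$scale,
        ncomp = as.integer(min(ncomp, fit$A)), rmsep = rmsep,
        cvR2 = cvR2, variant = variant)
}

#' Predict responses from a fitted PLS model
#'
#' @param model a \linkS4class{PLSModel}.
#' @param Xnew new predictor matrix with the training columns.
#' @param ncomp component count (default: the model's selection).
#' @return Predicted response matrix on the original response scale.
#' @export
predictPLS <- function(model, Xnew, ncomp = model@ncomp) {
    Xnew <- as.matrix(Xnew)
    Xs <- sweep(sweep(Xnew, 2L, model@xCenter), 2L, model@xScale, "/")
    yhat <- Xs %*% model@coefficients[, , ncomp]
    sweep(sweep(yhat, 2L, model@yScale, "*"), 2L, model@yCenter, "+")
}

#' Convenience wrapper: per-response leave-one-out R-squared
#'
#' Fits \code{\link{plsFit}} at a fixed component count and returns the
#' per-response LOO R-squared (1 - PRESS/TSS about the overall column
#' mean).
#'
#' @inheritParams plsFit
#' @param ncomp the component count to evaluate.
#' @return Named numeric vector of R-squared per response column.
#' @export
looCvR2 <- function(X, Y, ncomp, autoscale = TRUE) {
    plsFit(X, Y, ncomp = ncomp, autoscale = autoscale)@cvR2
}

#' Assemble predictor blocks for the regulation model
#'
#' The full model regresses the response matrix on negative-control
#' (input) occupancy plus all TF replicate occupancy columns; the null
#' model uses the input columns only, quantifying how much of the
#' apparent predictability is generic signal rather than TF-specific.
#'
#' @param xTF TF occupancy matrix (regions x TF replicates).
#' @param xInput control occupancy matrix (regions x control samples).
#' @param Y response matrix.
#' @param variant \code{"full"} or \code{"null"}.
#' @param ... passed to \code{\link{plsFit}}.
#' @return A \linkS4class{PLSModel}.
#' @export
regulationModel <- function(xTF, xInput, Y, variant = c("full", "null"),
                            ...) {
    variant <- match.arg(variant)
    X <- if (variant == "full") cbind(xInput, xTF) else
        as.matrix(xInput)
    plsFit(X, Y, variant = variant, ...)
}
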