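#' Normalize Jacobian maps to total brain volume
#'
#' Each subject's element values are divided by that subject's mean value
#' over the mask, removing global volume differences so the decomposition
#' is driven by local effects.
#'
#' @param maps an [ElementMaps-class] with voxel geometry.
#' @return The normalized [ElementMaps-class]; per-subject means become 1.
#' @export
normalizeJacobians <- function(maps) {
    stopifnot(is(maps, "ElementMaps"))
    if (!all(geometry(maps)$type == "voxel"))
        stop("normalizeJacobians requires voxel geometry")
    Y <- mapValues(maps)
    mu <- rowMeans(Y)
    if (any(mu <= 0))
        stop("nonpositive subject mean: cannot normalize to total volume")
    elementMaps(Y / mu, geometry(maps), gridShape(maps))
}

## random orthonormal K x K matrix
.randOrtho <- function(K) {
    qr.Q(qr(matrix(stats::rnorm(K * K), K, K)))
}

## symmetric decorrelation W <- (W W^T)^{-1/2} W
.symDecorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                       length(e$values)) %*% t(e$vectors) %*% W
}

## fixed-point ICA with logcosh contrast on whitened data Z (K x nSamples)
.fastICACore <- function(Z, tol, maxIter, seed) {
    K <- nrow(Z); E <- ncol(Z)
    W <- .withSeed(seed, .randOrtho(K))
    W <- .symDecorrelate(W)
    for (it in seq_len(maxIter)) {
        U <- W %*% Z
        G <- tanh(U)
        Gp <- 1 - G^2
        Wn <- (G %*% t(Z)) / E - diag(rowMeans(Gp), K) %*% W
        Wn <- .symDecorrelate(Wn)
        delta <- max(abs(abs(rowSums(Wn * W)) - 1))
        W <- Wn
        if (delta < tol) return(list(W = W, iterations = it,
                                     converged = TRUE))
    }
    list(W = W, iterations = maxIter, converged = FALSE)
}

.rowSkewness <- function(S) {
    mu <- rowMeans(S)
    sd <- sqrt(rowMeans((S - mu)^2))
    rowMeans((S - mu)^3) / sd^3
}

#' Decompose variant t-maps into impact modes
#'
#' Spatial independent component analysis of the variant x element
#' t-statistic matrix. Matching the convention for t-value inputs, no
#' per-element variance normalization or mean removal is applied: the raw
#' matrix is whitened within its rank-K principal subspace (SVD) and
#' unmixed by fixed-point ICA (logcosh contrast, symmetric decorrelation,
#' tolerance 1e-6, up to 1000 iterations, restarting with a fresh random
#' rotation up to 5 times on non-convergence). Each recovered spatial
#' source is oriented so its skewness over elements is positive (tie:
#' largest-|z| element positive), z-scored for reporting, and modes are
#' ordered by decreasing explained variance. The mixing matrix satisfies
#' `mixing %*% sources = ` rank-K projection of the input.
#'
#' @param tmat a [TStatMatrix-class] or a plain variants x elements matrix.
#' @param K number of modes (default 10).
#' @param seed initialization seed (ICA is stochastic in its starting
#'   rotation only).
#' @param tol convergence tolerance on the unmixing rotation.
#' @param maxIter iteration cap per restart.
#' @param maxRestarts restarts before giving up.
#' @return An [ImpactModeSet-class].
#' @export
decomposeModes <- function(tmat, K = 10L, seed = 1L, tol = 1e-6,
                           maxIter = 1000L, maxRestarts = 5L) {
    X <- if (is(tmat, "TStatMatrix")) tStats(tmat) else as.matrix(tmat)
    if (anyNA(X)) {
        drop <- rowSums(is.na(X)) > 0
        message(sprintf("decomposeModes: dropping %d rows with NA", sum(drop)))
        X <- X[!drop, , drop = FALSE]
    }
    V <- nrow(X); E <- ncol(X); K <- as.integer(K)
    if (K > min(V, E)) stop("K exceeds min(nVariants, nElements)")
    sv <- svd(X, nu = K, nv = K)
    if (K > sum(sv$d > max(sv$d) * 1e-12))
        stop("K exceeds the numerical rank of the t-matrix")
    ## principal-subspace whitening WITHOUT mean removal or variance
    ## normalization: Z has identity second moment over elements
    Z <- sqrt(E) * t(sv$v[, seq_len(K), drop = FALSE])
    fit <- NULL
    restarts <- 0L
    for (r in 0:maxRestarts) {
        fit <- .fastICACore(Z, tol, maxIter, childSeed(seed, paste0("ica", r)))
        restarts <- r
        if (fit$converged) break
    }
    if (!fit$converged)
        stop(sprintf(
            "ICA did not converge after %d restarts (last delta at %d iters)",
            maxRestarts, fit$iterations))
    S <- fit$W %*% Z                         # K x E raw sources
    ## mixing maps sources back to the rank-K projection of X:
    ## S = W * sqrt(E) * Vk' and W orthogonal give A = Uk Dk W' / sqrt(E)
    Uk <- sv$u[, seq_len(K), drop = FALSE]
    Dk <- diag(sv$d[seq_len(K)], K)
    A <- Uk %*% Dk %*% t(fit$W) / sqrt(E)
    ## sign convention: positive spatial skewness
    sk <- .rowSkewness(S)
    flip <- sk < 0 | (sk == 0 & apply(S, 1, function(z) z[which.max(abs(z))]) < 0)
    if (any(flip)) {
        S[flip, ] <- -S[flip, ]
        A[, flip] <- -A[, flip]
    }
    ## order modes by rank-1 contribution, descending
    contrib <- vapply(seq_len(K), function(k)
        sum(A[, k]^2) * sum(S[k, ]^2), numeric(1))
    ord <- order(contrib, decreasing = TRUE)
    S <- S[ord, , drop = FALSE]; A <- A[, ord, drop = FALSE]
    totSS <- sum(X^2)
    modeVar <- vapply(seq_len(K), function(k)
        sum(A[, k]^2) * sum(S[k, ]^2), numeric(1)) / totSS
    recon <- A %*% S
    vexp <- 1 - sum((X - recon)^2) / totSS
    mu <- rowMeans(S); sd <- sqrt(rowMeans((S - mu)^2))
    Sz <- (S - mu) / sd
    dimnames(Sz) <- list(paste0("mode", seq_len(K)), colnames(X))
    dimnames(S) <- dimnames(Sz)
    dimnames(A) <- list(rownames(X), rownames(Sz))
    new("ImpactModeSet", spatialMaps = Sz, sources = S, mixing = A,
        weightZ = .standardizeColumns(A),
        varianceExplainedTotal = max(0, min(1, vexp)),
        modeVariance = modeVar, K = K,
        convergence = list(iterations = fit$iterations, tolerance = tol,
                           restarts = restarts, seed = seed))
}

## column z-scores with population SD
.standardizeColumns <- function(A) {
    mu <- colMeans(A)
    sd <- sqrt(colMeans(sweep(A, 2, mu)^2))
    if (any(sd == 0)) stop("degenerate mode: constant mixing column")
    sweep(sweep(A, 2, mu), 2, sd, `/`)
}

#' Variant-wise mode weight z-scores
#'
#' Each mixing column is standardized over variants to mean 0 and
#' population SD 1, giving the per-variant "mode weight z-score" used to
#' rank which variants drive a mode.
#'
#' @param mixing variants x K mixing matrix (or an [ImpactModeSet-class]).
#' @return data.frame with columns `variant`, `mode`, `z`.
#' @export
modeWeights <- function(mixing) {
    A <- if (is(mixing, "ImpactModeSet")) mixing(mixing) else as.matrix(mixing)
    if (any(!is.finite(A))) stop("mixing matrix must be finite")
    Z <- .standardizeColumns(A)
    vid <- rownames(A)
    if (is.null(vid)) vid <- sprintf("var%05d", seq_len(nrow(A)))
    data.frame(
        variant = rep(vid, ncol(A)),
        mode = rep(seq_len(ncol(A)), each = nrow(A)),
        z = as.numeric(Z), stringsAsFactors = FALSE)
}

#' Variance explained by an impact-mode reconstruction
#'
#' `1 - ||X - mixing %*% sources||_F^2 / ||X||_F^2` with a zero-matrix
#' baseline (no mean removal, consistent with [decomposeModes()]); per-mode
#' fractions are the rank-1 term contributions.
#'
#' @param tmat the decomposed [TStatMatrix-class] or matrix.
#' @param modeset an [ImpactModeSet-class] (K = 0 gives total 0).
#' @return List with `total` and `perMode`.
#' @export
varianceExplained <- function(tmat, modeset) {
    X <- if (is(tmat, "TStatMatrix")) tStats(tmat) else as.matrix(tmat)
    X <- X[stats::complete.cases(X), , drop = FALSE]
    totSS <- sum(X^2)
    if (totSS == 0) stop("zero-norm t-matrix")
    if (modeset@K == 0L) return(list(total = 0, perMode = numeric(0)))
    A <- modeset@mixing; S <- modeset@sources
    recon <- A %*% S
    perMode <- vapply(seq_len(modeset@K), function(k)
        sum(A[, k]^2) * sum(S[k, ]^2), numeric(1)) / totSS
    list(total = 1 - sum((X - recon)^2) / totSS, perMode = perMode)
}

#' Match recovered modes to planted truth
#'
#' Greedy maximum-|correlation| bipartite matching of recovered spatial
#' maps to planted maps; reports per-pair spatial |r|, loading |r| and the
#' sign alignment of the matched pair.
#'
#' @param recovered an [ImpactModeSet-class].
#' @param truth a [SyntheticTruth-class].
#' @return data.frame with one row per matched pair: `mode`, `truthMode`,
#'   `spatialAbsR`, `loadingAbsR`, `sign`.
#' @export
matchModes <- function(recovered, truth) {
    R <- spatialMaps(recovered)
    Tm <- truth@spatialModes
    C <- stats::cor(t(R), t(Tm))
    nr <- nrow(R); nt <- nrow(Tm)
    res <- data.frame()
    Cw <- abs(C)
    AL <- mixing(recovered); TL <- truth@variantLoadings
    sameVariants <- nrow(AL) == nrow(TL)
    for (s in seq_len(min(nr, nt))) {
        ij <- arrayInd(which.max(Cw), dim(Cw))
        i <- ij[1]; j <- ij[2]
        lr <- if (sameVariants) abs(stats::cor(AL[, i], TL[, j])) else NA_real_
        res <- rbind(res, data.frame(
            mode = i, truthMode = j, spatialAbsR = abs(C[i, j]),
            loadingAbsR = lr, sign = sign(C[i, j])))
        Cw[i, ] <- -Inf; Cw[, j] <- -Inf
    }
    res[order(res$mode), , drop = FALSE]
}
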