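test_that("normalizeJacobians divides by each subject's mean over the mask", {
    cfg <- tinyConfig(seed = 3L)
    g <- genGenotypes(cfg); cv <- genCovariates(cfg); tr <- genTruth(cfg)
    maps <- genMaps(g, cv, tr, cfg)
    nm <- normalizeJacobians(maps)
    expect_equal(rowMeans(mapValues(nm)), rep(1, nrow(mapValues(nm))),
                 tolerance = 1e-12, ignore_attr = TRUE)
    ## constant subject map becomes all ones
    Y <- mapValues(maps); Y[1, ] <- 3.7
    nm2 <- normalizeJacobians(elementMaps(Y, geometry(maps), gridShape(maps)))
    expect_true(all(mapValues(nm2)[1, ] == 1))
    ## scale invariance per subject
    Y2 <- mapValues(maps); Y2[2, ] <- Y2[2, ] * 2
    nm3 <- normalizeJacobians(elementMaps(Y2, geometry(maps),
                                          gridShape(maps)))
    expect_equal(mapValues(nm3)[2, ], mapValues(nm)[2, ], tolerance = 1e-12)
    ## fixel geometry refused; nonpositive mean is a data error
    fx <- toyMaps(matrix(1, 4, 5))
    expect_error(normalizeJacobians(fx), "voxel")
    Yn <- mapValues(maps); Yn[1, ] <- -1
    expect_error(normalizeJacobians(
        elementMaps(Yn, geometry(maps), gridShape(maps))), "nonpositive")
})

test_that("noiseless planted sources are recovered nearly exactly", {
    pl <- plantedTMatrix(V = 60L, E = 600L, K = 4L, noiseSd = 0, seed = 5L)
    ms <- decomposeModes(pl$X, K = 4L, seed = 1L)
    mt <- matchModes(ms, pl$truth)
    expect_equal(nrow(mt), 4L)
    expect_true(all(mt$spatialAbsR >= 0.999))
    expect_true(all(mt$loadingAbsR >= 0.999))
    ## reconstruction reproduces the (here full-rank-K) input
    recon <- mixing(ms) %*% ms@sources
    expect_lt(max(abs(recon - pl$X)), 1e-8)
    ## variance explained is 1 at K = rank
    expect_equal(varianceExplained(pl$X, ms)$total, 1.0, tolerance = 1e-10)
})

test_that("K = 1 decomposition equals the first singular direction up to sign", {
    pl <- plantedTMatrix(V = 30L, E = 200L, K = 1L, noiseSd = 0.1, seed = 7L)
    ms <- decomposeModes(pl$X, K = 1L, seed = 2L)
    sv <- svd(pl$X, nu = 0, nv = 1)
    v1 <- sv$v[, 1]
    z1 <- (v1 - mean(v1)) / sqrt(mean((v1 - mean(v1))^2))
    expect_gte(abs(cor(spatialMaps(ms)[1, ], z1)), 1 - 1e-10)
    expect_equal(abs(spatialMaps(ms)[1, ]), abs(z1), tolerance = 1e-6,
                 ignore_attr = TRUE)
})

test_that("decomposition is equivariant to variant and element reordering", {
    pl <- plantedTMatrix(V = 40L, E = 300L, K = 3L, noiseSd = 0.05, seed = 9L)
    ms <- decomposeModes(pl$X, K = 3L, seed = 4L)
    ## permuting variant rows permutes mixing rows, spatial maps unchanged
    perm <- sample(nrow(pl$X))
    msP <- decomposeModes(pl$X[perm, ], K = 3L, seed = 4L)
    expect_equal(spatialMaps(msP), spatialMaps(ms), tolerance = 1e-6)
    expect_equal(mixing(msP), mixing(ms)[perm, ], tolerance = 1e-6,
                 ignore_attr = TRUE)
    ## permuting elements permutes the maps identically
    ep <- sample(ncol(pl$X))
    msE <- decomposeModes(pl$X[, ep], K = 3L, seed = 4L)
    expect_equal(spatialMaps(msE), spatialMaps(ms)[, ep], tolerance = 1e-4,
                 ignore_attr = TRUE)
})

test_that("spatial maps are z-scored and oriented to positive skewness", {
    pl <- plantedTMatrix(V = 40L, E = 400L, K = 3L, noiseSd = 0.05, seed = 13L)
    ms <- decomposeModes(pl$X, K = 3L, seed = 5L)
    S <- spatialMaps(ms)
    expect_equal(rowMeans(S), rep(0, 3), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(sqrt(rowMeans(S^2)), rep(1, 3), tolerance = 1e-6,
                 ignore_attr = TRUE)
    sk <- rowMeans(sweep(S, 1, rowMeans(S))^3)
    expect_true(all(sk >= 0))
})

test_that("mode weight z-scores standardize per column with population SD", {
    A <- cbind(a = c(1, 2, 3), b = c(5, 5, 8))
    z <- modeWeights(A)
    expect_equal(z$z[z$mode == 1], c(-1.2247449, 0, 1.2247449),
                 tolerance = 1e-6)
    ## location/scale invariance
    z2 <- modeWeights(cbind(2 * A[, 1] + 5, A[, 2]))
    expect_equal(z2$z, z$z, tolerance = 1e-12)
    ## degenerate constant column errors
    expect_error(modeWeights(cbind(c(1, 1, 1), c(1, 2, 3))), "degenerate")
})

test_that("variance explained accounts for the planted signal split", {
    ## constructed rank-3 + noise with a known SS split
    pl <- plantedTMatrix(V = 80L, E = 500L, K = 3L, noiseSd = 0, seed = 17L)
    sig <- pl$X
    set.seed(18)
    noise <- matrix(rnorm(length(sig), sd = 0.3), nrow(sig))
    X <- sig + noise
    ms <- decomposeModes(X, K = 3L, seed = 6L)
    ve <- varianceExplained(X, ms)
    expect_equal(ve$total, sum(sig^2) / sum(X^2), tolerance = 0.02)
    expect_equal(sum(ve$perMode), ve$total, tolerance = 0.02)
    ## K = 0 explains nothing
    empty <- new("ImpactModeSet",
                 spatialMaps = matrix(0, 0, ncol(X)),
                 sources = matrix(0, 0, ncol(X)),
                 mixing = matrix(0, nrow(X), 0),
                 weightZ = matrix(0, nrow(X), 0),
                 varianceExplainedTotal = 0, modeVariance = numeric(0),
                 K = 0L, convergence = list())
    expect_equal(varianceExplained(X, empty)$total, 0)
    expect_error(varianceExplained(X * 0, ms), "zero-norm")
})

test_that("recovery degrades monotonically with noise", {
    rec <- function(noiseSd) {
        mean(vapply(1:10, function(r) {
            pl <- plantedTMatrix(V = 50L, E = 400L, K = 3L,
                                 noiseSd = noiseSd, seed = 100L + r)
            ms <- decomposeModes(pl$X, K = 3L, seed = r)
            mean(matchModes(ms, pl$truth)$spatialAbsR)
        }, numeric(1)))
    }
    expect_gte(rec(0.2), rec(3))
})

test_that("a single-mode loader has an extreme weight z-score", {
    set.seed(23)
    pl <- plantedTMatrix(V = 100L, E = 400L, K = 3L, noiseSd = 0.05,
                         seed = 19L)
    ## make variant 7 load overwhelmingly on truth mode 2 only
    A <- pl$A; A[7, ] <- c(0, 12, 0)
    X <- A %*% pl$S + matrix(rnorm(100 * 400, sd = 0.05), 100)
    ms <- decomposeModes(X, K = 3L, seed = 8L)
    mt <- matchModes(ms, pl$truth)
    k <- mt$mode[mt$truthMode == 2]
    z <- abs(weightZ(ms)[, k])
    expect_gte(z[7], quantile(z, 0.95))
})

test_that("matching reports identity for truth vs itself and null for noise", {
    pl <- plantedTMatrix(V = 30L, E = 500L, K = 3L, noiseSd = 0, seed = 29L)
    selfSet <- new("ImpactModeSet",
                   spatialMaps = t(scale(t(pl$S)))[, ] *
                       sqrt(ncol(pl$S) / (ncol(pl$S) - 1)),
                   sources = pl$S, mixing = pl$A,
                   weightZ = apply(pl$A, 2, scale),
                   varianceExplainedTotal = 1, modeVariance = rep(1 / 3, 3),
                   K = 3L, convergence = list())
    mt <- matchModes(selfSet, pl$truth)
    expect_true(all(mt$spatialAbsR > 1 - 1e-10))
    ## permuted and flipped truth still matches perfectly
    flip <- new("ImpactModeSet",
                spatialMaps = selfSet@spatialMaps[c(2, 3, 1), ] *
                    c(-1, 1, -1),
                sources = pl$S[c(2, 3, 1), ] * c(-1, 1, -1),
                mixing = pl$A[, c(2, 3, 1)],
                weightZ = apply(pl$A, 2, scale)[, c(2, 3, 1)],
                varianceExplainedTotal = 1, modeVariance = rep(1 / 3, 3),
                K = 3L, convergence = list())
    mtf <- matchModes(flip, pl$truth)
    expect_true(all(mtf$spatialAbsR > 1 - 1e-10))
    expect_identical(mtf$truthMode[order(mtf$mode)], c(2L, 3L, 1L))
    ## random maps against truth: mean |r| near the null bound
    set.seed(31)
    rnd <- matrix(rnorm(3 * 500), 3)
    rndSet <- selfSet
    rndSet@spatialMaps <- t(apply(rnd, 1, function(v)
        (v - mean(v)) / sqrt(mean((v - mean(v))^2))))
    mtr <- matchModes(rndSet, pl$truth)
    expect_lt(mean(mtr$spatialAbsR), 3 / sqrt(500))
})
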