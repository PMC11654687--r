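## shared fixture builders; everything is generated in code

tinyConfig <- function(seed = 1L, ...) {
    args <- list(...)
    base <- list(nSubjects = 60L, nVariants = 30L,
                 gridShape = c(8L, 8L, 8L), nModes = 2L,
                 modeSparsity = 0.08, seed = seed)
    do.call(simConfig, utils::modifyList(base, args))
}

## genotype matrix straight from a dosage matrix, evenly spaced positions
toyGenotypes <- function(D, chrom = NULL, pos = NULL) {
    M <- ncol(D)
    if (is.null(colnames(D))) colnames(D) <- sprintf("var%05d", seq_len(M))
    if (is.null(rownames(D))) rownames(D) <- sprintf("S%04d", seq_len(nrow(D)))
    genotypeMatrix(D, data.frame(
        id = colnames(D),
        chrom = if (is.null(chrom)) rep(1L, M) else chrom,
        pos = if (is.null(pos)) seq_len(M) * 10000L else pos,
        ref = "A", alt = "G", stringsAsFactors = FALSE))
}

toySumstats <- function(ids, p, beta = 0.1, ea = "G", oa = "A") {
    summaryStats(data.frame(
        id = ids, effect_allele = ea, other_allele = oa,
        beta = rep_len(beta, length(ids)), se = 0.01, p = p,
        stringsAsFactors = FALSE))
}

## flat fixel-style maps with given value matrix
toyMaps <- function(Y) {
    E <- ncol(Y)
    if (is.null(colnames(Y))) colnames(Y) <- sprintf("fix%05d", seq_len(E))
    if (is.null(rownames(Y))) rownames(Y) <- sprintf("S%04d", seq_len(nrow(Y)))
    geom <- data.frame(element_id = colnames(Y), type = "fixel",
                       i = NA_integer_, j = NA_integer_, k = NA_integer_,
                       voxel_index = seq_len(E),
                       dir_x = 1, dir_y = 0, dir_z = 0,
                       stringsAsFactors = FALSE)
    elementMaps(Y, geom)
}

randomCovariates <- function(n, p = 5L, seed = 1L) {
    set.seed(seed)
    cv <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(cv) <- paste0("c", seq_len(p))
    rownames(cv) <- sprintf("S%04d", seq_len(n))
    cv
}

## independent full-design OLS oracle via lm(): t of x per element
lmOracleT <- function(Y, x, covariates) {
    vapply(seq_len(ncol(Y)), function(e) {
        fit <- lm(Y[, e] ~ x + ., data = as.data.frame(covariates))
        summary(fit)$coefficients["x", "t value"]
    }, numeric(1))
}

## planted mixture for mode-recovery tests: sparse independent sources
plantedTMatrix <- function(V, E, K, noiseSd = 0, seed = 1L) {
    set.seed(seed)
    S <- matrix(0, K, E)
    nAct <- floor(E / K)
    for (k in seq_len(K)) {
        sup <- ((k - 1L) * nAct + 1L):(k * nAct)
        ## heavy-tailed sparse source: super-Gaussian, good ICA target
        v <- rnorm(nAct)^3
        S[k, sup] <- v / sd(v)
    }
    A <- matrix(rnorm(V * K), V, K)
    rownames(A) <- sprintf("var%05d", seq_len(V))
    X <- A %*% S
    if (noiseSd > 0) X <- X + matrix(rnorm(V * E, sd = noiseSd), V, E)
    list(X = X, A = A, S = S,
        truth = new("SyntheticTruth", spatialModes = S, variantLoadings = A,
                    effectMaps = A %*% S, causalWeights = numeric(V)))
}
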