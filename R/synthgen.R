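#' Build a simulation configuration
#'
#' Default conditions: 500 subjects, 200 variants in LD blocks of 5 with
#' haplotype correlation 0.8, MAF drawn in 0.05-0.5, 3 planted spatial modes
#' on a 16x16x16 voxel grid with an ellipsoidal mask, 5% of elements active
#' per mode, 10% of variants loading on each mode, per-allele effect scale
#' 0.02 on a baseline of 1.0, and map noise SD 0.05.
#'
#' @param nSubjects,nVariants sample and variant counts.
#' @param mafRange ascending pair in (0, 0.5]; one MAF drawn per LD block.
#' @param ldBlockSize,ldDecay LD block length and within-block haplotype
#'   correlation; adjacent in-block variants are copies with allele-flip
#'   probability `(1 - ldDecay)/2`.
#' @param nModes number of planted modes K.
#' @param gridShape integer(3) voxel-grid dimensions.
#' @param nFixels element count for fixel geometry.
#' @param geometry `"voxel"` or `"fixel"`.
#' @param modeSparsity fraction of elements active per mode.
#' @param loadingSparsity fraction of variants loading per mode.
#' @param effectScale per-allele effect scale (see [genMaps()]).
#' @param causalSd SD of nonzero liability weights (see [genSumstats()]).
#' @param noiseSd map noise SD.
#' @param covariateEffects named numeric of global covariate slopes; names
#'   must be covariate-table columns.
#' @param seed master seed.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nSubjects = 50, nVariants = 20, seed = 1)
#' g <- genGenotypes(cfg)
#' @export
simConfig <- function(nSubjects = 500L, nVariants = 200L,
                      mafRange = c(0.05, 0.5), ldBlockSize = 5L,
                      ldDecay = 0.8, nModes = 3L,
                      gridShape = c(16L, 16L, 16L), nFixels = 2000L,
                      geometry = c("voxel", "fixel"),
                      modeSparsity = 0.05, loadingSparsity = 0.1,
                      effectScale = 0.02, causalSd = 0.15,
                      noiseSd = 0.05,
                      covariateEffects = c(age = 5e-4, sex = 5e-3),
                      seed = 1L) {
    geometry <- match.arg(geometry)
    new("SimConfig",
        nSubjects = as.integer(nSubjects), nVariants = as.integer(nVariants),
        mafRange = as.numeric(mafRange), ldBlockSize = as.integer(ldBlockSize),
        ldDecay = as.numeric(ldDecay), nModes = as.integer(nModes),
        gridShape = as.integer(gridShape), nFixels = as.integer(nFixels),
        geometry = geometry, modeSparsity = as.numeric(modeSparsity),
        loadingSparsity = as.numeric(loadingSparsity),
        effectScale = as.numeric(effectScale), causalSd = as.numeric(causalSd),
        noiseSd = as.numeric(noiseSd),
        covariateEffects = covariateEffects, seed = as.integer(seed))
}

## haplotype-level block simulation; returns subjects x variants 0/1 matrix
.simHaplotype <- function(nSubjects, mafs, blockStarts, flipP) {
    M <- length(mafs)
    H <- matrix(0L, nSubjects, M)
    isStart <- logical(M); isStart[blockStarts] <- TRUE
    for (m in seq_len(M)) {
        if (isStart[m]) {
            H[, m] <- stats::rbinom(nSubjects, 1L, mafs[m])
        } else {
            flip <- stats::rbinom(nSubjects, 1L, flipP)
            H[, m] <- (H[, m - 1L] + flip) %% 2L
        }
    }
    H
}

#' Generate block-LD hard-call dosage genotypes
#'
#' Two haplotypes per subject are simulated per LD block: the block head is
#' Bernoulli(MAF), and each subsequent variant copies its left neighbour
#' with allele-flip probability `(1 - ldDecay)/2`, giving dosage correlation
#' `ldDecay^distance` within a block and no LD across block boundaries.
#' Dosages are hard calls (0/1/2); fractional dosages in `[0, 2]` are
#' accepted everywhere downstream. Variants are laid out at 10-kb spacing,
#' blocks contiguous, filled block-wise across up to 22 chromosomes.
#'
#' @param cfg a [SimConfig-class].
#' @param seed optional override of the derived child seed.
#' @return A [GenotypeMatrix-class]; metadata `maf` records the requested
#'   (block-head) MAF and `info` is 1.0.
#' @export
genGenotypes <- function(cfg, seed = childSeed(cfg@seed, "genotypes")) {
    stopifnot(is(cfg, "SimConfig"))
    if (cfg@nVariants < 1L) stop("nVariants must be positive")
    S <- cfg@nSubjects; M <- cfg@nVariants; B <- cfg@ldBlockSize
    nBlocks <- ceiling(M / B)
    blockStarts <- seq(1L, M, by = B)
    flipP <- (1 - cfg@ldDecay) / 2
    .withSeed(seed, {
        blockMaf <- stats::runif(nBlocks, cfg@mafRange[1], cfg@mafRange[2])
        mafs <- rep(blockMaf, each = B, length.out = M)
        H1 <- .simHaplotype(S, mafs, blockStarts, flipP)
        H2 <- .simHaplotype(S, mafs, blockStarts, flipP)
        D <- H1 + H2
        storage.mode(D) <- "double"
        alleles <- t(vapply(seq_len(M), function(i)
            sample(c("A", "C", "G", "T"), 2L), character(2)))
        blocksPerChrom <- ceiling(nBlocks / 22L)
        blockChrom <- (seq_len(nBlocks) - 1L) %/% blocksPerChrom + 1L
        chrom <- rep(blockChrom, each = B, length.out = M)
        pos <- integer(M)
        for (cc in unique(chrom)) {
            idx <- which(chrom == cc)
            pos[idx] <- seq_along(idx) * 10000L
        }
        vid <- sprintf("var%05d", seq_len(M))
        dimnames(D) <- list(sprintf("S%04d", seq_len(S)), vid)
        genotypeMatrix(D, data.frame(
            id = vid, chrom = chrom, pos = pos,
            ref = alleles[, 1], alt = alleles[, 2],
            maf = mafs, info = 1.0, stringsAsFactors = FALSE))
    })
}

#' Generate the subject covariate table
#'
#' Columns follow the standard imaging-genetics confound set: age (uniform
#' 45-82 years), sex (0/1), age^2, age x sex, age^2 x sex, 10 standard-normal
#' genomic-ancestry principal-component stand-ins, three dummy columns for
#' four imaging sites, and a binary preprocessing-batch flag.
#'
#' @param cfg a [SimConfig-class] (only `nSubjects` and `seed` used).
#' @param seed optional child-seed override.
#' @return data.frame with one row per subject (rownames = subject ids).
#' @export
genCovariates <- function(cfg, seed = childSeed(cfg@seed, "covariates")) {
    stopifnot(is(cfg, "SimConfig"), cfg@nSubjects >= 2L)
    S <- cfg@nSubjects
    .withSeed(seed, {
        age <- stats::runif(S, 45, 82)
        sex <- stats::rbinom(S, 1L, 0.5)
        pcs <- matrix(stats::rnorm(S * 10L), S, 10L,
                      dimnames = list(NULL, paste0("PC", 1:10)))
        site <- sample.int(4L, S, replace = TRUE)
        siteD <- vapply(2:4, function(k) as.integer(site == k), integer(S))
        colnames(siteD) <- paste0("site", 2:4)
        out <- data.frame(age = age, sex = sex, age2 = age^2,
                          age_sex = age * sex, age2_sex = age^2 * sex,
                          pcs, siteD,
                          batch = stats::rbinom(S, 1L, 0.2))
        rownames(out) <- sprintf("S%04d", seq_len(S))
        out
    })
}

.ellipsoidMask <- function(gridShape) {
    d <- gridShape
    ax <- lapply(1:3, function(i) ((seq_len(d[i]) - 0.5) / d[i] - 0.5) * 2)
    r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
    array(r2 <= 1, dim = d)
}

.makeGeometry <- function(cfg, seed) {
    if (cfg@geometry == "voxel") {
        mask <- .ellipsoidMask(cfg@gridShape)
        idx <- which(mask, arr.ind = TRUE) - 1L  # 0-based grid indices
        E <- nrow(idx)
        data.frame(element_id = sprintf("vox%05d", seq_len(E)),
                   type = "voxel", i = idx[, 1], j = idx[, 2], k = idx[, 3],
                   voxel_index = NA_integer_,
                   dir_x = NA_real_, dir_y = NA_real_, dir_z = NA_real_,
                   stringsAsFactors = FALSE)
    } else {
        E <- cfg@nFixels
        .withSeed(seed, {
            dirs <- matrix(stats::rnorm(E * 3L), E, 3L)
            dirs <- dirs / sqrt(rowSums(dirs^2))
            data.frame(element_id = sprintf("fix%05d", seq_len(E)),
                       type = "fixel", i = NA_integer_, j = NA_integer_,
                       k = NA_integer_,
                       voxel_index = sample.int(prod(cfg@gridShape), E,
                                                replace = TRUE),
                       dir_x = dirs[, 1], dir_y = dirs[, 2], dir_z = dirs[, 3],
                       stringsAsFactors = FALSE)
        })
    }
}

.smooth1d <- function(x, w = 3L) {
    as.numeric(stats::filter(x, rep(1 / w, w), sides = 2,
                             circular = TRUE))
}

#' Plant the ground-truth mode structure
#'
#' K spatial modes occupy disjoint contiguous stretches of the element list
#' (contiguity in grid order keeps voxel modes spatially coherent). Support
#' values are smoothed Gaussian noise, centred to sum to zero (so modes with
#' disjoint supports are exactly uncorrelated) and scaled to unit SD over
#' the support. Variant loadings are sparse Gaussian; each mode keeps at
#' least one loading variant. Liability weights for the discovery-GWAS
#' simulation are sparse Gaussian with SD `causalSd` on ~10% of variants.
#'
#' @param cfg a [SimConfig-class].
#' @param seed optional child-seed override.
#' @return A [SyntheticTruth-class].
#' @export
genTruth <- function(cfg, seed = childSeed(cfg@seed, "truth")) {
    stopifnot(is(cfg, "SimConfig"))
    geom <- .makeGeometry(cfg, childSeed(cfg@seed, "geometry"))
    E <- nrow(geom); K <- cfg@nModes; M <- cfg@nVariants
    if (K > min(M, E))
        stop("nModes exceeds the rank budget min(nVariants, nElements)")
    nActive <- max(2L, round(cfg@modeSparsity * E))
    if (K * nActive > E)
        stop("mode supports do not fit: reduce nModes or modeSparsity")
    .withSeed(seed, {
        modes <- matrix(0, K, E)
        ## disjoint contiguous supports spread over the element list
        starts <- floor((seq_len(K) - 1L) * E / K) + 1L
        for (k in seq_len(K)) {
            sup <- starts[k]:(starts[k] + nActive - 1L)
            v <- .smooth1d(stats::rnorm(nActive))
            v <- v - mean(v)
            s <- stats::sd(v) * sqrt((nActive - 1) / nActive)
            if (s < 1e-12) { v[1] <- 1; v[2] <- -1; s <- stats::sd(v) }
            modes[k, sup] <- v / s
        }
        loadings <- matrix(0, M, K)
        nLoad <- max(1L, round(cfg@loadingSparsity * M))
        for (k in seq_len(K)) {
            who <- sample.int(M, nLoad)
            loadings[who, k] <- stats::rnorm(nLoad)
        }
        ## mode-loading variants also dispose to the trait (plus a sparse
        ## background), so top discovery-GWAS variants carry the planted
        ## brain structure, as in the study design being emulated
        loaders <- which(rowSums(loadings != 0) > 0)
        bg <- sample.int(M, max(1L, round(0.05 * M)))
        causal <- union(loaders, bg)
        w <- numeric(M)
        w[causal] <- stats::rnorm(length(causal), sd = cfg@causalSd)
        dimnames(loadings) <- list(sprintf("var%05d", seq_len(M)),
                                   paste0("mode", seq_len(K)))
        dimnames(modes) <- list(paste0("mode", seq_len(K)), geom$element_id)
        new("SyntheticTruth", spatialModes = modes,
            variantLoadings = loadings,
            effectMaps = loadings %*% modes, causalWeights = w)
    })
}

#' Generate subject brain maps with planted variant effects
#'
#' Each map is `1.0 + centeredDosage %*% (effectScale * effectMaps) +
#' covariateShift + noise`, where the covariate shift is
#' `covariates %*% covariateEffects` applied uniformly over elements (a
#' global, head-size-like nuisance) and the noise is iid Gaussian with SD
#' `noiseSd`. Dosages are centred per variant, so the baseline is
#' MAF-independent.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param covariates covariate data.frame from [genCovariates()].
#' @param truth a [SyntheticTruth-class].
#' @param cfg the [SimConfig-class] used to generate them.
#' @param seed optional child-seed override.
#' @return An [ElementMaps-class] with voxel or fixel geometry per config.
#' @export
genMaps <- function(genotypes, covariates, truth, cfg,
                    seed = childSeed(cfg@seed, "maps")) {
    stopifnot(is(genotypes, "GenotypeMatrix"), is(truth, "SyntheticTruth"))
    D <- dosages(genotypes)
    if (nrow(D) != nrow(covariates))
        stop("dimension mismatch: genotypes and covariates disagree on subjects")
    if (ncol(D) != nrow(truth@effectMaps))
        stop("dimension mismatch: genotypes and truth disagree on variants")
    geom <- .makeGeometry(cfg, childSeed(cfg@seed, "geometry"))
    E <- nrow(geom)
    if (ncol(truth@effectMaps) != E)
        stop("dimension mismatch: truth and geometry disagree on elements")
    Dc <- scale(D, center = TRUE, scale = FALSE)
    V <- matrix(1.0, nrow(D), E)
    V <- V + Dc %*% (cfg@effectScale * truth@effectMaps)
    ce <- cfg@covariateEffects
    ce <- ce[names(ce) %in% colnames(covariates)]
    if (length(ce)) {
        shift <- as.matrix(covariates[, names(ce), drop = FALSE]) %*% ce
        V <- V + matrix(shift, nrow(D), E)
    }
    if (cfg@noiseSd > 0)
        V <- V + .withSeed(seed,
            matrix(stats::rnorm(length(V), sd = cfg@noiseSd), nrow(V)))
    rownames(V) <- rownames(D)
    elementMaps(V, geom,
                if (cfg@geometry == "voxel") cfg@gridShape else integer(0))
}

#' Simulate discovery-GWAS summary statistics
#'
#' An independent discovery cohort of `nDiscovery` subjects is generated
#' with the same genotype model; liability is
#' `centeredDosage %*% causalWeights + N(0, 1)` and each variant is tested
#' by marginal OLS of liability on its dosage. The effect allele is the alt
#' allele.
#'
#' @param genotypes target-sample [GenotypeMatrix-class] (supplies the
#'   variant metadata; dosages themselves are re-simulated).
#' @param truth a [SyntheticTruth-class] (supplies `causalWeights`).
#' @param cfg the [SimConfig-class].
#' @param nDiscovery discovery-cohort size (>= 10).
#' @param seed optional child-seed override.
#' @return A [SummaryStats-class] with beta, se and two-sided p per variant.
#' @export
genSumstats <- function(genotypes, truth, cfg, nDiscovery = 10000L,
                        seed = childSeed(cfg@seed, "sumstats")) {
    stopifnot(nDiscovery >= 10L)
    dcfg <- cfg
    dcfg@nSubjects <- as.integer(nDiscovery)
    gDisc <- genGenotypes(dcfg, seed = childSeed(seed, "discovery-genotypes"))
    D <- dosages(gDisc)
    n <- nrow(D)
    y <- as.numeric(D %*% truth@causalWeights) +
        .withSeed(childSeed(seed, "liability"), stats::rnorm(n))
    Dc <- scale(D, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    sxx <- colSums(Dc^2)
    sxy <- as.numeric(crossprod(Dc, yc))
    beta <- ifelse(sxx > 0, sxy / sxx, 0)
    sse <- sum(yc^2) - beta^2 * sxx
    sse <- pmax(sse, 0)
    se <- ifelse(sxx > 0, sqrt(sse / (n - 2) / sxx), Inf)
    tt <- ifelse(is.finite(se) & se > 0, beta / se, 0)
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    v <- variantInfo(genotypes)
    summaryStats(data.frame(
        id = v$id, effect_allele = v$alt, other_allele = v$ref,
        beta = beta, se = se, p = p, stringsAsFactors = FALSE))
}

#' Generate a kinship pair table
#'
#' `nRelatedPairs` unordered subject pairs receive kinship coefficients
#' drawn from \{0.25, 0.125, 0.0625\} (full sibling / second- /
#' third-degree), plus an equal number of sub-threshold pairs with kinship
#' uniform in (0.005, 0.043).
#'
#' @param nSubjects subject-pool size.
#' @param nRelatedPairs number of related pairs (kinship >= 0.044).
#' @param seed integer seed.
#' @return data.frame with columns `id1`, `id2`, `kinship`; no unordered
#'   pair appears twice.
#' @export
genKinship <- function(nSubjects, nRelatedPairs, seed = 1L) {
    stopifnot(nRelatedPairs <= nSubjects * (nSubjects - 1) / 2)
    ids <- sprintf("S%04d", seq_len(nSubjects))
    if (nRelatedPairs == 0L)
        return(data.frame(id1 = character(0), id2 = character(0),
                          kinship = numeric(0), stringsAsFactors = FALSE))
    .withSeed(seed, {
        nWant <- nRelatedPairs * 2L
        seen <- character(0)
        p1 <- character(0); p2 <- character(0)
        while (length(p1) < nWant) {
            a <- sample.int(nSubjects, 1L); b <- sample.int(nSubjects, 1L)
            if (a == b) next
            key <- paste(min(a, b), max(a, b))
            if (key %in% seen) next
            seen <- c(seen, key)
            p1 <- c(p1, ids[min(a, b)]); p2 <- c(p2, ids[max(a, b)])
        }
        kin <- c(sample(c(0.25, 0.125, 0.0625), nRelatedPairs, replace = TRUE),
                 stats::runif(nRelatedPairs, 0.005, 0.043))
        data.frame(id1 = p1, id2 = p2, kinship = kin,
                   stringsAsFactors = FALSE)
    })
}
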