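#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Simulation configuration
#'
#' Parameters of the synthetic imaging-genetics generator. The generator
#' plants a low-rank (modes x loadings) effect structure in subject brain
#' maps driven by simulated allele dosages, so every downstream stage of the
#' pipeline (QC, clumping, polygenic scoring, mass-univariate GLM,
#' permutation inference, impact-mode decomposition) can be validated
#' against known ground truth.
#'
#' @slot nSubjects number of target-sample subjects.
#' @slot nVariants number of variants.
#' @slot mafRange length-2 numeric in (0, 0.5]; one minor-allele frequency is
#'   drawn uniformly per LD block.
#' @slot ldBlockSize variants per LD block; adjacent variants within a block
#'   are haplotype copies with allele-flip probability `(1 - ldDecay)/2`.
#' @slot ldDecay within-block haplotype correlation parameter in `[0, 1)`
#'   (1 is allowed and means exact copies).
#' @slot nModes number of planted spatial modes K.
#' @slot gridShape length-3 integer voxel-grid dimensions (voxel geometry).
#' @slot nFixels number of fixel elements (fixel geometry).
#' @slot geometry `"voxel"` or `"fixel"`.
#' @slot modeSparsity fraction of elements active in each planted mode.
#' @slot loadingSparsity fraction of variants loading on each mode.
#' @slot effectScale per-allele effect scale multiplying the planted
#'   loadings; sets the simulation signal-to-noise ratio together with
#'   `noiseSd`.
#' @slot causalSd standard deviation of nonzero per-variant liability
#'   weights used by the discovery-GWAS simulation.
#' @slot noiseSd additive Gaussian noise SD on map values.
#' @slot covariateEffects named numeric; global (element-uniform) slope per
#'   covariate column.
#' @slot seed integer master seed; all generators derive child seeds from it.
#' @export
setClass("SimConfig", representation(
    nSubjects = "integer", nVariants = "integer",
    mafRange = "numeric", ldBlockSize = "integer", ldDecay = "numeric",
    nModes = "integer", gridShape = "integer", nFixels = "integer",
    geometry = "character", modeSparsity = "numeric",
    loadingSparsity = "numeric", effectScale = "numeric",
    causalSd = "numeric", noiseSd = "numeric",
    covariateEffects = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character(0)
    cnt <- c(nSubjects = object@nSubjects, nVariants = object@nVariants,
             ldBlockSize = object@ldBlockSize, nModes = object@nModes)
    if (any(cnt < 1L))
        msg <- c(msg, paste0("counts must be >= 1: ",
                             paste(names(cnt)[cnt < 1L], collapse = ", ")))
    if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
        any(object@mafRange > 0.5) || diff(object@mafRange) < 0)
        msg <- c(msg, "mafRange must be an ascending pair within (0, 0.5]")
    if (object@ldDecay < 0 || object@ldDecay > 1)
        msg <- c(msg, "ldDecay must lie in [0, 1]")
    for (s in c("modeSparsity", "loadingSparsity")) {
        v <- slot(object, s)
        if (v <= 0 || v > 1) msg <- c(msg, paste(s, "must lie in (0, 1]"))
    }
    if (!object@geometry %in% c("voxel", "fixel"))
        msg <- c(msg, "geometry must be 'voxel' or 'fixel'")
    if (object@geometry == "voxel" && length(object@gridShape) != 3L)
        msg <- c(msg, "gridShape must have 3 dimensions")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Subject-by-variant allele dosages with variant metadata
#'
#' @slot dosages numeric matrix, subjects x variants, values in `[0, 2]`
#'   (expected count of the alt allele); dimnames give subject and variant
#'   ids.
#' @slot variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `maf`, `info`.
#' @export
setClass("GenotypeMatrix", representation(
    dosages = "matrix", variants = "data.frame"
))

setValidity("GenotypeMatrix", function(object) {
    msg <- character(0)
    d <- object@dosages
    v <- object@variants
    need <- c("id", "chrom", "pos", "ref", "alt", "maf", "info")
    if (!all(need %in% names(v)))
        msg <- c(msg, paste("variants must have columns:",
                            paste(setdiff(need, names(v)), collapse = ", ")))
    else {
        if (ncol(d) != nrow(v))
            msg <- c(msg, "ncol(dosages) must equal nrow(variants)")
        if (anyDuplicated(v$id)) msg <- c(msg, "variant ids must be unique")
        if (any(v$pos < 0)) msg <- c(msg, "positions must be nonnegative")
    }
    if (length(d) && (min(d, na.rm = TRUE) < 0 || max(d, na.rm = TRUE) > 2))
        msg <- c(msg, "dosages must lie in [0, 2]")
    if (is.null(rownames(d)) || is.null(colnames(d)))
        msg <- c(msg, "dosages must carry subject and variant ids as dimnames")
    if (length(msg)) msg else TRUE
})

#' Discovery-GWAS summary statistics
#'
#' @slot stats data.frame with columns `id`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `p` (p in (0, 1]).
#' @export
setClass("SummaryStats", representation(stats = "data.frame"))

setValidity("SummaryStats", function(object) {
    s <- object@stats
    need <- c("id", "effect_allele", "other_allele", "beta", "se", "p")
    if (!all(need %in% names(s)))
        return(paste("stats must have columns:",
                     paste(setdiff(need, names(s)), collapse = ", ")))
    msg <- character(0)
    if (any(s$p <= 0 | s$p > 1, na.rm = TRUE))
        msg <- c(msg, "p-values must lie in (0, 1]")
    if (any(s$effect_allele == s$other_allele))
        msg <- c(msg, "effect and other allele must differ per variant")
    if (anyDuplicated(s$id)) msg <- c(msg, "variant ids must be unique")
    if (length(msg)) msg else TRUE
})

#' Per-subject polygenic score
#'
#' @slot score named numeric, one value per subject.
#' @slot weightSetId character label of the weight set used.
#' @slot nVariantsUsed number of variants that entered the score.
#' @export
setClass("PGSVector", representation(
    score = "numeric", weightSetId = "character", nVariantsUsed = "integer"
))

setValidity("PGSVector", function(object) {
    if (any(!is.finite(object@score))) "scores must be finite" else TRUE
})

#' Subject-by-element brain measure matrix with geometry
#'
#' Elements are voxels inside a mask on a 3-D grid (tensor-based-morphometry
#' Jacobian-determinant values), or fixels (specific fiber populations
#' within voxels, carrying a unit direction; apparent-fiber-density values).
#'
#' @slot values numeric matrix, subjects x elements; dimnames give subject
#'   and element ids.
#' @slot geometry data.frame, one row per element: `element_id`, `type`
#'   ("voxel"/"fixel"), 0-based grid indices `i`, `j`, `k` (voxel), and
#'   `voxel_index`, `dir_x`, `dir_y`, `dir_z` (fixel; unit direction).
#' @slot gridShape integer(3) grid dimensions for voxel geometry,
#'   integer(0) otherwise.
#' @export
setClass("ElementMaps", representation(
    values = "matrix", geometry = "data.frame", gridShape = "integer"
))

setValidity("ElementMaps", function(object) {
    msg <- character(0)
    if (nrow(object@geometry) != ncol(object@values))
        msg <- c(msg, "geometry must have one row per element")
    if (length(object@values) && !all(is.finite(object@values)))
        msg <- c(msg, "map values must be finite")
    g <- object@geometry
    if (nrow(g) && any(g$type == "fixel")) {
        dirs <- as.matrix(g[g$type == "fixel", c("dir_x", "dir_y", "dir_z")])
        nrm <- sqrt(rowSums(dirs^2))
        if (any(abs(nrm - 1) > 1e-6))
            msg <- c(msg, "fixel direction vectors must have unit norm")
    }
    if (length(msg)) msg else TRUE
})

#' Predictor-by-element t-statistics
#'
#' One row per predictor (a polygenic score or a single variant's dosage),
#' one column per brain element, from covariate-adjusted OLS fits.
#'
#' @slot t numeric matrix, predictors x elements.
#' @slot beta matching matrix of effect estimates.
#' @slot partialR2 matching matrix of partial r-squared, `t^2/(t^2 + df)`.
#' @slot df residual degrees of freedom (subjects minus model columns).
#' @slot model character descriptor of the fitted model.
#' @export
setClass("TStatMatrix", representation(
    t = "matrix", beta = "matrix", partialR2 = "matrix",
    df = "numeric", model = "character"
))

setValidity("TStatMatrix", function(object) {
    msg <- character(0)
    if (object@df <= 0) msg <- c(msg, "residual df must be positive")
    for (s in c("beta", "partialR2")) {
        m <- slot(object, s)
        if (length(m) && !identical(dim(m), dim(object@t)))
            msg <- c(msg, paste(s, "must match dim(t)"))
    }
    if (length(msg)) msg else TRUE
})

#' Max-statistic permutation result
#'
#' Family-wise-error-corrected p-values from the permutation distribution of
#' the maximum statistic over elements (no cluster enhancement).
#'
#' @slot p per-element FWE-corrected p-values.
#' @slot tObs observed t-statistics.
#' @slot nullMax permutation distribution of the max statistic.
#' @slot nPerm number of permutations.
#' @slot seed permutation seed.
#' @slot tail "two", "left" or "right".
#' @export
setClass("FweResult", representation(
    p = "numeric", tObs = "numeric", nullMax = "numeric",
    nPerm = "integer", seed = "integer", tail = "character"
))

setValidity("FweResult", function(object) {
    msg <- character(0)
    lo <- 1 / (object@nPerm + 1)
    if (any(object@p < lo - 1e-12 | object@p > 1 + 1e-12))
        msg <- c(msg, "p must lie in [1/(nPerm+1), 1]")
    if (length(object@nullMax) != object@nPerm)
        msg <- c(msg, "nullMax must have nPerm entries")
    if (length(msg)) msg else TRUE
})

#' Impact-mode decomposition result
#'
#' K spatially independent component maps extracted from a variant x element
#' t-statistic matrix, with the variant-wise mixing weights that combine
#' them back into the rank-K part of the input.
#'
#' @slot spatialMaps K x elements, each map z-scored over elements.
#' @slot sources K x elements raw (unscaled) independent sources; the
#'   reconstruction `mixing %*% sources` equals the rank-K principal-subspace
#'   projection of the input.
#' @slot mixing variants x K mixing matrix.
#' @slot weightZ variants x K mixing weights standardized per mode
#'   (mean 0, population SD 1 over variants).
#' @slot varianceExplainedTotal fraction of squared norm of the input
#'   reproduced by the reconstruction (zero-matrix baseline: no mean
#'   removal).
#' @slot modeVariance per-mode rank-1 squared-norm fractions.
#' @slot K number of modes.
#' @slot convergence list with iterations, tolerance, restarts, seed.
#' @export
setClass("ImpactModeSet", representation(
    spatialMaps = "matrix", sources = "matrix", mixing = "matrix",
    weightZ = "matrix", varianceExplainedTotal = "numeric",
    modeVariance = "numeric", K = "integer", convergence = "list"
))

setValidity("ImpactModeSet", function(object) {
    msg <- character(0)
    K <- object@K
    if (K > 0L) {
        if (nrow(object@spatialMaps) != K || nrow(object@sources) != K ||
            ncol(object@mixing) != K)
            msg <- c(msg, "spatialMaps/sources/mixing must have K modes")
        mu <- rowMeans(object@spatialMaps)
        sd1 <- sqrt(rowMeans(object@spatialMaps^2) - mu^2)
        if (any(abs(mu) > 1e-8) || any(abs(sd1 - 1) > 1e-6))
            msg <- c(msg, "spatial maps must be z-scored over elements")
    }
    v <- object@varianceExplainedTotal
    if (v < -1e-10 || v > 1 + 1e-10)
        msg <- c(msg, "varianceExplainedTotal must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Planted ground truth of the synthetic generator
#'
#' @slot spatialModes K x elements planted source maps (disjoint supports,
#'   zero-sum within support, unit SD over support).
#' @slot variantLoadings variants x K sparse Gaussian loadings.
#' @slot effectMaps variants x elements, exactly
#'   `variantLoadings %*% spatialModes`.
#' @slot causalWeights per-variant true effect on the scalar liability used
#'   by the discovery-GWAS simulation.
#' @export
setClass("SyntheticTruth", representation(
    spatialModes = "matrix", variantLoadings = "matrix",
    effectMaps = "matrix", causalWeights = "numeric"
))

setValidity("SyntheticTruth", function(object) {
    msg <- character(0)
    rec <- object@variantLoadings %*% object@spatialModes
    if (!isTRUE(all.equal(rec, object@effectMaps, tolerance = 1e-12,
                          check.attributes = FALSE)))
        msg <- c(msg, "effectMaps must equal variantLoadings %*% spatialModes")
    if (any(rowSums(object@spatialModes != 0) == 0))
        msg <- c(msg, "every spatial mode needs at least one nonzero element")
    if (length(msg)) msg else TRUE
})

#' Pipeline run configuration
#'
#' Stage toggles, thresholds and seeds for [runPipeline()]. Defaults mirror
#' standard imaging-genetics practice: MAF 0.01, imputation info 0.7, HWE p
#' 1e-7, kinship 0.044, clumping at p < 0.01 / r^2 < 0.1 / 500 kb,
#' 5000 permutations, K = 10 modes.
#'
#' @slot params named list; see [runConfig()] for the keys.
#' @export
setClass("RunConfig", representation(params = "list"))
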