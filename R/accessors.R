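#' @rdname GenotypeMatrix-class
#' @param dosages subjects x variants dosage matrix with dimnames.
#' @param variants variant metadata data.frame (`id`, `chrom`, `pos`, `ref`,
#'   `alt`, `maf`, `info`); `maf`/`info` are filled from the dosages (empirical
#'   alt-allele-based MAF) and 1.0 when absent.
#' @return A [GenotypeMatrix-class] object.
#' @export
genotypeMatrix <- function(dosages, variants) {
    dosages <- as.matrix(dosages)
    variants <- as.data.frame(variants, stringsAsFactors = FALSE)
    if (is.null(colnames(dosages))) colnames(dosages) <- variants$id
    if (is.null(rownames(dosages)))
        rownames(dosages) <- sprintf("S%04d", seq_len(nrow(dosages)))
    if (is.null(variants$maf)) {
        af <- colMeans(dosages) / 2
        variants$maf <- pmin(af, 1 - af)
    }
    if (is.null(variants$info)) variants$info <- 1.0
    new("GenotypeMatrix", dosages = dosages, variants = variants)
}

#' @rdname SummaryStats-class
#' @param stats data.frame of per-variant statistics.
#' @return A [SummaryStats-class] object.
#' @export
summaryStats <- function(stats) {
    new("SummaryStats", stats = as.data.frame(stats, stringsAsFactors = FALSE))
}

#' @rdname ElementMaps-class
#' @param values subjects x elements matrix.
#' @param geometry element geometry data.frame.
#' @param gridShape integer(3) for voxel geometry.
#' @return An [ElementMaps-class] object.
#' @export
elementMaps <- function(values, geometry, gridShape = integer(0)) {
    values <- as.matrix(values)
    if (is.null(colnames(values))) colnames(values) <- geometry$element_id
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
    new("ElementMaps", values = values,
        geometry = as.data.frame(geometry, stringsAsFactors = FALSE),
        gridShape = as.integer(gridShape))
}

## --- accessors ---------------------------------------------------------

#' Accessors for pipeline objects
#'
#' @param x an object of the matching class.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypeMatrix", function(x) x@variants)

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setMethod("subjectIds", "GenotypeMatrix", function(x) rownames(x@dosages))
#' @rdname accessors
#' @export
setMethod("subjectIds", "ElementMaps", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setGeneric("sumStats", function(x) standardGeneric("sumStats"))
#' @rdname accessors
#' @export
setMethod("sumStats", "SummaryStats", function(x) x@stats)

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setMethod("mapValues", "ElementMaps", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setMethod("geometry", "ElementMaps", function(x) x@geometry)

#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname accessors
#' @export
setMethod("gridShape", "ElementMaps", function(x) x@gridShape)

#' @rdname accessors
#' @export
setGeneric("tStats", function(x) standardGeneric("tStats"))
#' @rdname accessors
#' @export
setMethod("tStats", "TStatMatrix", function(x) x@t)

#' @rdname accessors
#' @export
setGeneric("residualDf", function(x) standardGeneric("residualDf"))
#' @rdname accessors
#' @export
setMethod("residualDf", "TStatMatrix", function(x) x@df)

#' @rdname accessors
#' @export
setGeneric("partialR2", function(x) standardGeneric("partialR2"))
#' @rdname accessors
#' @export
setMethod("partialR2", "TStatMatrix", function(x) x@partialR2)

#' @rdname accessors
#' @export
setGeneric("effectSizes", function(x) standardGeneric("effectSizes"))
#' @rdname accessors
#' @export
setMethod("effectSizes", "TStatMatrix", function(x) x@beta)

#' @rdname accessors
#' @export
setGeneric("fweP", function(x) standardGeneric("fweP"))
#' @rdname accessors
#' @export
setMethod("fweP", "FweResult", function(x) x@p)

#' @rdname accessors
#' @export
setGeneric("nullMaxima", function(x) standardGeneric("nullMaxima"))
#' @rdname accessors
#' @export
setMethod("nullMaxima", "FweResult", function(x) x@nullMax)

#' @rdname accessors
#' @export
setGeneric("pgsScores", function(x) standardGeneric("pgsScores"))
#' @rdname accessors
#' @export
setMethod("pgsScores", "PGSVector", function(x) x@score)

#' @rdname accessors
#' @export
setGeneric("spatialMaps", function(x) standardGeneric("spatialMaps"))
#' @rdname accessors
#' @export
setMethod("spatialMaps", "ImpactModeSet", function(x) x@spatialMaps)
#' @rdname accessors
#' @export
setMethod("spatialMaps", "SyntheticTruth", function(x) x@spatialModes)

#' @rdname accessors
#' @export
setGeneric("mixing", function(x) standardGeneric("mixing"))
#' @rdname accessors
#' @export
setMethod("mixing", "ImpactModeSet", function(x) x@mixing)

#' @rdname accessors
#' @export
setGeneric("weightZ", function(x) standardGeneric("weightZ"))
#' @rdname accessors
#' @export
setMethod("weightZ", "ImpactModeSet", function(x) x@weightZ)

#' @rdname accessors
#' @export
setGeneric("nModes", function(x) standardGeneric("nModes"))
#' @rdname accessors
#' @export
setMethod("nModes", "ImpactModeSet", function(x) x@K)

#' @rdname accessors
#' @export
setGeneric("varianceExplainedTotal",
           function(x) standardGeneric("varianceExplainedTotal"))
#' @rdname accessors
#' @export
setMethod("varianceExplainedTotal", "ImpactModeSet",
          function(x) x@varianceExplainedTotal)

#' @rdname accessors
#' @export
setGeneric("variantLoadings", function(x) standardGeneric("variantLoadings"))
#' @rdname accessors
#' @export
setMethod("variantLoadings", "SyntheticTruth", function(x) x@variantLoadings)

#' @rdname accessors
#' @export
setGeneric("effectMaps", function(x) standardGeneric("effectMaps"))
#' @rdname accessors
#' @export
setMethod("effectMaps", "SyntheticTruth", function(x) x@effectMaps)

#' @rdname accessors
#' @export
setGeneric("causalWeights", function(x) standardGeneric("causalWeights"))
#' @rdname accessors
#' @export
setMethod("causalWeights", "SyntheticTruth", function(x) x@causalWeights)

## --- show methods ------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nSubjects, "subjects x", object@nVariants,
        "variants,", object@nModes, "planted modes,",
        object@geometry, "geometry\n")
    cat("  MAF", paste(format(object@mafRange), collapse = "-"),
        "| LD blocks of", object@ldBlockSize, "decay", object@ldDecay,
        "| noise SD", object@noiseSd, "| seed", object@seed, "\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
    cat("GenotypeMatrix:", nrow(object@dosages), "subjects x",
        ncol(object@dosages), "variants\n")
    if (nrow(object@variants)) {
        cat("  chrom:", paste(unique(object@variants$chrom), collapse = " "),
            "| MAF range:",
            paste(format(range(object@variants$maf), digits = 3),
                  collapse = "-"), "\n")
    }
})

setMethod("show", "SummaryStats", function(object) {
    s <- object@stats
    cat("SummaryStats:", nrow(s), "variants; min p =",
        format(suppressWarnings(min(s$p)), digits = 3), "\n")
})

setMethod("show", "PGSVector", function(object) {
    cat("PGSVector '", object@weightSetId, "': ", length(object@score),
        " subjects, ", object@nVariantsUsed, " variants used\n", sep = "")
})

setMethod("show", "ElementMaps", function(object) {
    cat("ElementMaps:", nrow(object@values), "subjects x",
        ncol(object@values), "elements (",
        paste(unique(object@geometry$type), collapse = "/"), ")\n")
    if (length(object@gridShape))
        cat("  grid:", paste(object@gridShape, collapse = " x "), "\n")
})

setMethod("show", "TStatMatrix", function(object) {
    cat("TStatMatrix:", nrow(object@t), "predictors x", ncol(object@t),
        "elements, df =", object@df, "\n  model:", object@model, "\n")
})

setMethod("show", "FweResult", function(object) {
    cat("FweResult:", length(object@p), "elements,", object@nPerm,
        "permutations (", object@tail, "-tailed ), ",
        sum(object@p < 0.05), "elements with FWE p < 0.05\n")
})

setMethod("show", "ImpactModeSet", function(object) {
    cat("ImpactModeSet: K =", object@K, "modes over",
        ncol(object@spatialMaps), "elements,",
        nrow(object@mixing), "variants\n")
    cat("  variance explained:",
        sprintf("%.1f%%", 100 * object@varianceExplainedTotal),
        "( per mode:",
        paste(sprintf("%.1f", 100 * object@modeVariance), collapse = " "),
        "%)\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", nrow(object@spatialModes), "modes,",
        nrow(object@variantLoadings), "variants,",
        ncol(object@spatialModes), "elements\n")
})

setMethod("show", "RunConfig", function(object) {
    cat("RunConfig with", length(object@params), "parameters\n")
})
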