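## TSV dialect: tab-separated, header row, plain UTF-8. Written with
## full double precision so write/read round-trips are value-exact.

.fwrite <- function(df, path) {
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
}

.fread <- function(path) {
    as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Genotype TSV writers and readers
#'
#' `writeGenotypes` writes `genotypes.tsv` (subjects x variants; first
#' column `subject_id`, remaining columns named by variant id) and
#' `variants.tsv` (id, chrom, pos, ref, alt, maf, info) into `dir`;
#' `readGenotypes` reads them back.
#'
#' @param g a [GenotypeMatrix-class].
#' @param dir directory.
#' @return `readGenotypes` returns a [GenotypeMatrix-class].
#' @export
writeGenotypes <- function(g, dir) {
    D <- dosages(g)
    .fwrite(data.frame(subject_id = rownames(D), D, check.names = FALSE),
            file.path(dir, "genotypes.tsv"))
    .fwrite(variantInfo(g), file.path(dir, "variants.tsv"))
    invisible(NULL)
}

#' @rdname writeGenotypes
#' @export
readGenotypes <- function(dir) {
    gt <- .fread(file.path(dir, "genotypes.tsv"))
    v <- .fread(file.path(dir, "variants.tsv"))
    D <- as.matrix(gt[, -1, drop = FALSE])
    rownames(D) <- gt$subject_id
    genotypeMatrix(D, v)
}

#' Summary-statistics, covariate and kinship TSV I/O
#'
#' Plain TSV round-trip for the remaining tabular inputs of the pipeline.
#'
#' @param ss a [SummaryStats-class]; `covariates` a data.frame with subject
#'   rownames; `kinship` a data.frame (`id1`, `id2`, `kinship`).
#' @param path file path.
#' @return Readers return the corresponding object.
#' @name tabular-io
NULL

#' @rdname tabular-io
#' @export
writeSumstats <- function(ss, path) {
    .fwrite(sumStats(ss), path); invisible(NULL)
}

#' @rdname tabular-io
#' @export
readSumstats <- function(path) summaryStats(.fread(path))

#' @rdname tabular-io
#' @param covariates covariate data.frame.
#' @export
writeCovariates <- function(covariates, path) {
    .fwrite(data.frame(subject_id = rownames(covariates), covariates,
                       check.names = FALSE), path)
    invisible(NULL)
}

#' @rdname tabular-io
#' @export
readCovariates <- function(path) {
    d <- .fread(path)
    rownames(d) <- d$subject_id
    d$subject_id <- NULL
    d
}

#' @rdname tabular-io
#' @param kinship kinship pair data.frame.
#' @export
writeKinship <- function(kinship, path) { .fwrite(kinship, path); invisible(NULL) }

#' @rdname tabular-io
#' @export
readKinship <- function(path) .fread(path)

#' Element-map I/O
#'
#' Voxel geometry: a 4-D NIfTI volume (subject as 4th axis), a 3-D mask
#' NIfTI, and a subject-id text file. Fixel geometry: a `fixels.tsv`
#' geometry table (`element_id`, `voxel_index`, `dir_x`, `dir_y`, `dir_z`)
#' and an `afd.tsv` value table (first column `subject_id`). `writeMaps`
#' writes the set appropriate to the geometry into `dir` using `prefix`;
#' `readMaps` reads it back.
#'
#' @param maps an [ElementMaps-class].
#' @param dir directory.
#' @param prefix file-name prefix (default "maps").
#' @param geometryType `"voxel"` or `"fixel"` for `readMaps`.
#' @return `readMaps` returns an [ElementMaps-class].
#' @export
writeMaps <- function(maps, dir, prefix = "maps") {
    g <- geometry(maps)
    Y <- mapValues(maps)
    if (all(g$type == "voxel")) {
        gs <- gridShape(maps)
        arr <- array(0, dim = c(gs, nrow(Y)))
        lin <- (g$i + 1L) + gs[1] * g$j + gs[1] * gs[2] * g$k
        vol <- prod(gs)
        for (s in seq_len(nrow(Y))) arr[lin + (s - 1L) * vol] <- Y[s, ]
        mask <- array(0L, dim = gs); mask[lin] <- 1L
        RNifti::writeNifti(RNifti::asNifti(arr),
                           file.path(dir, paste0(prefix, ".nii.gz")))
        RNifti::writeNifti(RNifti::asNifti(mask),
                           file.path(dir, paste0(prefix, "_mask.nii.gz")))
        writeLines(rownames(Y), file.path(dir, paste0(prefix, "_subjects.txt")))
    } else {
        .fwrite(g[, c("element_id", "voxel_index",
                      "dir_x", "dir_y", "dir_z")],
                file.path(dir, paste0(prefix, "_fixels.tsv")))
        .fwrite(data.frame(subject_id = rownames(Y), Y, check.names = FALSE),
                file.path(dir, paste0(prefix, "_afd.tsv")))
    }
    invisible(NULL)
}

#' @rdname writeMaps
#' @export
readMaps <- function(dir, prefix = "maps",
                     geometryType = c("voxel", "fixel")) {
    geometryType <- match.arg(geometryType)
    if (geometryType == "voxel") {
        arr <- RNifti::readNifti(file.path(dir, paste0(prefix, ".nii.gz")))
        mask <- RNifti::readNifti(file.path(dir,
                                            paste0(prefix, "_mask.nii.gz")))
        subs <- readLines(file.path(dir, paste0(prefix, "_subjects.txt")))
        if (dim(arr)[4] != length(subs))
            stop("subject-count mismatch between image and subject list")
        gs <- dim(mask)
        idx <- which(mask != 0, arr.ind = TRUE)
        lin <- idx[, 1] + gs[1] * (idx[, 2] - 1L) +
            gs[1] * gs[2] * (idx[, 3] - 1L)
        vol <- prod(gs)
        Y <- t(vapply(seq_along(subs), function(s)
            as.numeric(arr[lin + (s - 1L) * vol]), numeric(nrow(idx))))
        rownames(Y) <- subs
        geom <- data.frame(
            element_id = sprintf("vox%05d", seq_len(nrow(idx))),
            type = "voxel", i = idx[, 1] - 1L, j = idx[, 2] - 1L,
            k = idx[, 3] - 1L, voxel_index = NA_integer_,
            dir_x = NA_real_, dir_y = NA_real_, dir_z = NA_real_,
            stringsAsFactors = FALSE)
        elementMaps(Y, geom, gs)
    } else {
        fx <- .fread(file.path(dir, paste0(prefix, "_fixels.tsv")))
        nrm <- sqrt(fx$dir_x^2 + fx$dir_y^2 + fx$dir_z^2)
        if (any(abs(nrm - 1) > 1e-6))
            stop("fixel table contains non-unit direction vectors")
        av <- .fread(file.path(dir, paste0(prefix, "_afd.tsv")))
        Y <- as.matrix(av[, -1, drop = FALSE])
        rownames(Y) <- av$subject_id
        geom <- data.frame(
            element_id = fx$element_id, type = "fixel",
            i = NA_integer_, j = NA_integer_, k = NA_integer_,
            voxel_index = fx$voxel_index,
            dir_x = fx$dir_x, dir_y = fx$dir_y, dir_z = fx$dir_z,
            stringsAsFactors = FALSE)
        elementMaps(Y, geom)
    }
}

#' t-matrix TSV I/O
#'
#' Predictor x element t-statistics as TSV (first column `predictor`, then
#' one column per element); degrees of freedom and model descriptor stored
#' in `#`-prefixed header comments.
#'
#' @param tmat a [TStatMatrix-class].
#' @param path file path.
#' @return `readTStats` returns a [TStatMatrix-class] (t only; beta and
#'   partial r^2 are not round-tripped).
#' @export
writeTStats <- function(tmat, path) {
    con <- file(path, "w")
    writeLines(c(sprintf("# df=%.17g", tmat@df),
                 sprintf("# model=%s", tmat@model)), con)
    close(con)
    suppressWarnings(utils::write.table(
        data.frame(predictor = rownames(tmat@t), tmat@t,
                   check.names = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
    invisible(NULL)
}

#' @rdname writeTStats
#' @export
readTStats <- function(path) {
    hdr <- readLines(path, n = 2L)
    df <- as.numeric(sub("# df=", "", hdr[1], fixed = TRUE))
    model <- sub("# model=", "", hdr[2], fixed = TRUE)
    d <- utils::read.delim(path, skip = 2L, check.names = FALSE)
    t <- as.matrix(d[, -1, drop = FALSE])
    rownames(t) <- d$predictor
    new("TStatMatrix", t = t, beta = matrix(numeric(0), 0, 0),
        partialR2 = t^2 / (t^2 + df), df = df, model = model)
}

#' Write / read the planted-truth archive
#'
#' Internal plain-text format: `truth_modes.tsv` (mode x element),
#' `truth_loadings.tsv` (variant x mode) and `truth_causal.tsv`; the
#' variant x element effect-map product is reconstructed on read.
#'
#' @param truth a [SyntheticTruth-class].
#' @param dir directory.
#' @return `readTruth` returns a [SyntheticTruth-class].
#' @export
writeTruth <- function(truth, dir) {
    .fwrite(data.frame(mode = seq_len(nrow(truth@spatialModes)),
                       truth@spatialModes, check.names = FALSE),
            file.path(dir, "truth_modes.tsv"))
    .fwrite(data.frame(variant = rownames(truth@variantLoadings),
                       truth@variantLoadings, check.names = FALSE),
            file.path(dir, "truth_loadings.tsv"))
    .fwrite(data.frame(variant = rownames(truth@variantLoadings),
                       weight = truth@causalWeights),
            file.path(dir, "truth_causal.tsv"))
    invisible(NULL)
}

#' @rdname writeTruth
#' @export
readTruth <- function(dir) {
    md <- .fread(file.path(dir, "truth_modes.tsv"))
    ld <- .fread(file.path(dir, "truth_loadings.tsv"))
    cz <- .fread(file.path(dir, "truth_causal.tsv"))
    modes <- as.matrix(md[, -1, drop = FALSE])
    loadings <- as.matrix(ld[, -1, drop = FALSE])
    rownames(loadings) <- ld$variant
    new("SyntheticTruth", spatialModes = modes, variantLoadings = loadings,
        effectMaps = loadings %*% modes, causalWeights = cz$weight)
}
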