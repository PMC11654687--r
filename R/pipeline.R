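#' Build a pipeline run configuration
#'
#' Thresholds default to standard imaging-genetics settings: MAF >= 0.01,
#' imputation info > 0.7, HWE p > 1e-7, kinship 0.044, clumping at
#' p < 0.01 / r^2 < 0.1 / 500 kb, 5000 permutations, two-sided inference,
#' K = 10 impact modes.
#'
#' @param simulate generate synthetic inputs (the only input mode shipped;
#'   external data are supplied by constructing the objects directly).
#' @param sim a [SimConfig-class] used when `simulate` is TRUE.
#' @param mafMin,infoMin,hwePMin QC thresholds.
#' @param kinshipThreshold relatedness-pruning threshold.
#' @param clumpP,clumpR2,clumpKb clumping parameters.
#' @param pgsThresholds clumping-and-thresholding grid.
#' @param optimize select the PGS by its top IDP association.
#' @param idpDims principal-component IDP dimensionalities.
#' @param nPerm,tail permutation settings.
#' @param K impact-mode count.
#' @param headSizeAdjust,globalAfdAdjust,logJacobian adjustment flags.
#' @param normalizeToBrainVolume divide each subject's Jacobian map by its
#'   mean before the mode decomposition.
#' @param seed master seed.
#' @return A [RunConfig-class].
#' @export
runConfig <- function(simulate = TRUE, sim = simConfig(),
                      mafMin = 0.01, infoMin = 0.7, hwePMin = 1e-7,
                      kinshipThreshold = 0.044,
                      clumpP = 0.01, clumpR2 = 0.1, clumpKb = 500,
                      pgsThresholds = c(1e-4, 1e-3, 0.01, 0.05, 0.5, 1),
                      optimize = TRUE, idpDims = c(2L, 5L),
                      nPerm = 5000L, tail = "two", K = 10L,
                      headSizeAdjust = FALSE, globalAfdAdjust = FALSE,
                      logJacobian = FALSE, normalizeToBrainVolume = TRUE,
                      seed = 1L) {
    stopifnot(mafMin >= 0, mafMin <= 0.5, infoMin >= 0, infoMin <= 1,
              hwePMin >= 0, hwePMin < 1, kinshipThreshold >= 0,
              clumpP > 0, clumpP <= 1, clumpR2 >= 0, clumpR2 <= 1,
              clumpKb > 0, nPerm >= 100, K >= 1,
              tail %in% c("two", "left", "right"))
    p <- list(simulate = simulate, sim = sim, mafMin = mafMin,
              infoMin = infoMin, hwePMin = hwePMin,
              kinshipThreshold = kinshipThreshold, clumpP = clumpP,
              clumpR2 = clumpR2, clumpKb = clumpKb,
              pgsThresholds = pgsThresholds, optimize = optimize,
              idpDims = as.integer(idpDims), nPerm = as.integer(nPerm),
              tail = tail, K = as.integer(K),
              headSizeAdjust = headSizeAdjust,
              globalAfdAdjust = globalAfdAdjust,
              logJacobian = logJacobian,
              normalizeToBrainVolume = normalizeToBrainVolume,
              seed = as.integer(seed))
    new("RunConfig", params = p)
}

## SimConfig <-> named list of plain values, for serialization
.simToList <- function(s) {
    nm <- slotNames("SimConfig")
    stats::setNames(lapply(nm, function(n) slot(s, n)), nm)
}

.simFromList <- function(l) do.call(simConfig, l)

#' Write / read a run configuration as plain text
#'
#' Each parameter is serialized on one `key = deparse(value)` line, so the
#' round-trip is exact (including doubles).
#'
#' @param cfg a [RunConfig-class].
#' @param path file path.
#' @return `readRunConfig` returns a [RunConfig-class].
#' @export
writeRunConfig <- function(cfg, path) {
    p <- cfg@params
    p$sim <- .simToList(p$sim)
    lines <- vapply(names(p), function(k)
        paste0(k, " = ", paste(deparse(p[[k]], control = "all"),
                               collapse = "")), character(1))
    writeLines(lines, path)
    invisible(NULL)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    lines <- readLines(path)
    p <- list()
    for (ln in lines) {
        k <- sub(" = .*$", "", ln)
        p[[k]] <- eval(parse(text = sub("^[^=]+= ", "", ln)),
                       envir = baseenv())
    }
    p$sim <- .simFromList(p$sim)
    new("RunConfig", params = p)
}

.stageLog <- function(log, stage, ...) {
    message(sprintf("[%s] %s", stage, paste(..., collapse = " ")))
    c(log, stage)
}

#' Run the full imaging-genetics pipeline
#'
#' Executes, in order: simulate (synthetic inputs), QC, relatedness
#' pruning, clumping, polygenic scoring (grid + optional IDP optimization),
#' GLM (PGS map and per-variant maps for the clumped variants), permutation
#' FWE on the PGS predictor, impact-mode decomposition of the variant
#' t-matrix, and report assembly. All artifacts are written into `outDir`
#' together with a JSON manifest (package version, serialized config, all
#' derived seeds, per-stage counts).
#'
#' @param cfg a [RunConfig-class].
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage outputs and the
#'   manifest; `outDir` holds the serialized artifacts.
#' @export
runPipeline <- function(cfg, outDir) {
    stopifnot(is(cfg, "RunConfig"))
    p <- cfg@params
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    stages <- character(0)
    counts <- list()
    if (!p$simulate)
        stop("external-input mode is not wired into runPipeline; construct ",
             "the stage objects directly with the module functions")

    ## 1. simulate
    sim <- p$sim
    g0 <- genGenotypes(sim)
    cov <- genCovariates(sim)
    truth <- genTruth(sim)
    maps <- genMaps(g0, cov, truth, sim)
    ss <- genSumstats(g0, truth, sim)
    kin <- genKinship(sim@nSubjects, max(1L, sim@nSubjects %/% 50L),
                      seed = childSeed(sim@seed, "kinship"))
    writeGenotypes(g0, outDir)
    writeCovariates(cov, file.path(outDir, "covariates.tsv"))
    writeSumstats(ss, file.path(outDir, "sumstats.tsv"))
    writeKinship(kin, file.path(outDir, "kinship.tsv"))
    writeTruth(truth, outDir)
    writeMaps(maps, outDir)
    counts$simulate <- c(subjects = sim@nSubjects, variants = sim@nVariants,
                         elements = ncol(mapValues(maps)))
    stages <- .stageLog(stages, "simulate",
                        sim@nSubjects, "subjects,", sim@nVariants,
                        "variants,", ncol(mapValues(maps)), "elements")

    ## 2. qc
    g <- qcFilter(g0, p$mafMin, p$infoMin, p$hwePMin)
    counts$qc <- attr(g, "qcLog")
    stages <- .stageLog(stages, "qc", ncol(dosages(g)), "variants kept")

    ## 3. prune relatedness
    kept <- pruneRelatedness(kin, p$kinshipThreshold,
                             subjects = subjectIds(g))
    g <- genotypeMatrix(dosages(g)[kept, , drop = FALSE], variantInfo(g))
    cov <- cov[kept, , drop = FALSE]
    maps <- elementMaps(mapValues(maps)[kept, , drop = FALSE],
                        geometry(maps), gridShape(maps))
    counts$prune <- c(subjects_kept = length(kept))
    stages <- .stageLog(stages, "prune", length(kept), "subjects kept")

    ## 4. clump
    idx <- clumpVariants(ss, g, p$clumpP, p$clumpR2, p$clumpKb)
    writeLines(idx, file.path(outDir, "clump_indices.txt"))
    counts$clump <- c(indices = length(idx))
    stages <- .stageLog(stages, "clump", length(idx), "index variants")

    ## 5. pgs
    fam <- pgsGrid(ss, g, p$pgsThresholds, clumpFirst = TRUE,
                   r2Thresh = p$clumpR2, windowKb = p$clumpKb)
    if (p$optimize) {
        idps <- idpExtract(maps, p$idpDims)
        sel <- optimizePGS(fam, idps, cov)
        pgs <- sel$pgs
        .fwrite(data.frame(candidate = rownames(sel$tGrid), sel$tGrid,
                           check.names = FALSE),
                file.path(outDir, "pgs_idp_tgrid.tsv"))
    } else {
        pgs <- fam[[length(fam)]]
        sel <- list(best = pgs@weightSetId)
    }
    .fwrite(data.frame(subject_id = names(pgsScores(pgs)),
                       pgs = pgsScores(pgs)),
            file.path(outDir, "pgs.tsv"))
    counts$pgs <- c(candidates = length(fam))
    stages <- .stageLog(stages, "pgs", "selected", sel$best)

    ## 6. glm
    if (p$normalizeToBrainVolume && all(geometry(maps)$type == "voxel"))
        mapsAnalysis <- normalizeJacobians(maps)
    else mapsAnalysis <- maps
    design <- buildDesign(
        cov,
        headSize = if (p$headSizeAdjust) rowMeans(mapValues(maps)) else NULL,
        globalAfd = if (p$globalAfdAdjust) rowMeans(mapValues(maps)) else NULL,
        logTransform = p$logJacobian)
    tPgs <- fitGLM(mapsAnalysis, pgsScores(pgs), design, predictorId = "pgs")
    vIds <- intersect(idx, variantInfo(g)$id)
    tVar <- variantTMaps(g, vIds, mapsAnalysis, design, ss = ss)
    writeTStats(tPgs, file.path(outDir, "tmap_pgs.tsv"))
    writeTStats(tVar, file.path(outDir, "tmap_variants.tsv"))
    counts$glm <- c(variants_mapped = length(vIds), df = tPgs@df)
    stages <- .stageLog(stages, "glm", length(vIds),
                        "variant maps, df =", tPgs@df)

    ## 7. permutation FWE
    fwe <- permutationFWE(mapsAnalysis, pgsScores(pgs), design,
                          nPerm = p$nPerm,
                          seed = childSeed(p$seed, "fwe"), tail = p$tail)
    .fwrite(data.frame(element_id = names(fweP(fwe)), t = fwe@tObs,
                       fwe_p = fweP(fwe)),
            file.path(outDir, "fwe_pgs.tsv"))
    .fwrite(data.frame(perm = seq_len(fwe@nPerm), max_stat = nullMaxima(fwe)),
            file.path(outDir, "fwe_null_maxima.tsv"))
    counts$permute <- c(n_perm = fwe@nPerm,
                        significant = sum(fweP(fwe) < 0.05))
    stages <- .stageLog(stages, "permute", sum(fweP(fwe) < 0.05),
                        "elements at FWE p < 0.05")

    ## 8. impact modes
    K <- min(p$K, length(vIds) - 1L, ncol(mapValues(maps)))
    ms <- decomposeModes(tVar, K = K, seed = childSeed(p$seed, "ica"))
    .fwrite(modeWeights(ms), file.path(outDir, "mode_weights.tsv"))
    .fwrite(data.frame(mode = rownames(spatialMaps(ms)), spatialMaps(ms),
                       check.names = FALSE),
            file.path(outDir, "mode_maps.tsv"))
    ve <- varianceExplained(tVar, ms)
    counts$modes <- c(K = K, variance_explained = ve$total)
    stages <- .stageLog(stages, "modes", K, "modes,",
                        sprintf("%.1f%%", 100 * ve$total),
                        "variance explained")

    ## manifest + report
    cfgPath <- file.path(outDir, "config.txt")
    writeRunConfig(cfg, cfgPath)
    manifest <- list(
        package = "impactmodes",
        version = as.character(utils::packageVersion("impactmodes")),
        stages = c(stages, "report"),
        seeds = list(master = p$seed, sim = sim@seed,
                     fwe = childSeed(p$seed, "fwe"),
                     ica = childSeed(p$seed, "ica")),
        config_sha = unname(tools::md5sum(cfgPath)),
        counts = lapply(counts, as.list))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stages <- .stageLog(stages, "report", "manifest written")
    invisible(list(genotypes = g, covariates = cov, truth = truth,
                   maps = maps, sumstats = ss, clumpIndices = idx,
                   pgs = pgs, pgsSelection = sel, tPgs = tPgs, tVar = tVar,
                   fwe = fwe, modes = ms, manifest = manifest))
}

#' Summarize a completed pipeline run
#'
#' Reads the artifacts in a run directory and prints QC attrition, clump
#' counts, the PGS-IDP selection grid, top FWE-significant elements, mode
#' variance explained, and the top-|z| variants per mode. Missing stage
#' outputs produce a partial report with warnings.
#'
#' @param runDir directory written by [runPipeline()].
#' @param topN rows to show in the top-element / top-variant tables.
#' @return Invisibly, a list of the report tables.
#' @export
runReport <- function(runDir, topN = 5L) {
    out <- list()
    manifestPath <- file.path(runDir, "manifest.json")
    if (!file.exists(manifestPath)) {
        warning("no manifest found; reporting what exists")
    } else {
        out$manifest <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
        cat("Pipeline run:", paste(out$manifest$stages, collapse = " -> "),
            "\n")
        qc <- out$manifest$counts$qc
        if (!is.null(qc))
            cat(sprintf(
                "QC: %d -> %d variants (MAF %d, info %d, HWE %d removed)\n",
                qc[["n_in"]], qc[["n_out"]], qc[["fail_maf"]],
                qc[["fail_info"]], qc[["fail_hwe"]]))
    }
    cl <- file.path(runDir, "clump_indices.txt")
    if (file.exists(cl)) {
        out$clumpIndices <- readLines(cl)
        cat("Clumping:", length(out$clumpIndices), "index variants\n")
    } else warning("clump output missing")
    tg <- file.path(runDir, "pgs_idp_tgrid.tsv")
    if (file.exists(tg)) {
        out$tGrid <- .fread(tg)
        cat("PGS-IDP |t| maxima by candidate:\n")
        mx <- apply(abs(as.matrix(out$tGrid[, -1])), 1, max)
        for (i in seq_along(mx))
            cat(sprintf("  %-10s max|t| = %.2f\n", out$tGrid$candidate[i],
                        mx[i]))
    }
    fw <- file.path(runDir, "fwe_pgs.tsv")
    if (file.exists(fw)) {
        out$fwe <- .fread(fw)
        sig <- out$fwe[out$fwe$fwe_p < 0.05, , drop = FALSE]
        cat("FWE:", nrow(sig), "elements significant at p < 0.05\n")
        if (nrow(sig)) {
            sig <- sig[order(sig$fwe_p, -abs(sig$t)), , drop = FALSE]
            print(utils::head(sig, topN), row.names = FALSE)
        }
    } else warning("FWE output missing")
    mw <- file.path(runDir, "mode_weights.tsv")
    if (file.exists(mw)) {
        out$modeWeights <- .fread(mw)
        ks <- sort(unique(out$modeWeights$mode))
        ve <- if (!is.null(out$manifest))
            out$manifest$counts$modes[["variance_explained"]] else NA
        cat(sprintf("Impact modes: K = %d, variance explained = %s\n",
                    length(ks),
                    ifelse(is.na(ve), "?", sprintf("%.1f%%", 100 * as.numeric(ve)))))
        out$topVariants <- do.call(rbind, lapply(ks, function(k) {
            w <- out$modeWeights[out$modeWeights$mode == k, ]
            w <- w[order(-abs(w$z)), ][seq_len(min(topN, nrow(w))), ]
            cat(sprintf("  mode %d top variants: %s\n", k,
                        paste(sprintf("%s (z=%.1f)", w$variant, w$z),
                              collapse = ", ")))
            w
        }))
    } else warning("mode output missing")
    invisible(out)
}
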