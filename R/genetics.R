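#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson 1-df goodness-of-fit test of observed genotype counts against the
#' expected proportions p^2 : 2pq : q^2 at the allele frequency estimated
#' from the counts. Returns p = 1 when an allele is fixed (the test is
#' degenerate for a monomorphic variant).
#'
#' @param nAA,nAa,naa genotype counts (AA homozygote, heterozygote, aa
#'   homozygote).
#' @return The chi-square p-value.
#' @examples
#' hweTest(25, 50, 25)  # exact HWE proportions: p = 1
#' hweTest(50, 0, 50)   # no heterozygotes: chi-square = 100
#' @export
hweTest <- function(nAA, nAa, naa) {
    if (any(c(nAA, nAa, naa) < 0)) stop("genotype counts must be nonnegative")
    n <- nAA + nAa + naa
    if (n < 1) stop("at least one genotype observation required")
    pA <- (2 * nAA + nAa) / (2 * n)
    if (pA <= 0 || pA >= 1) return(1.0)  # fixed allele, degenerate
    exp <- n * c(pA^2, 2 * pA * (1 - pA), (1 - pA)^2)
    chi2 <- sum((c(nAA, nAa, naa) - exp)^2 / exp)
    stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

## HWE p-values for all variants from hard-called dosages
.hweFromDosages <- function(D) {
    G <- round(D)
    vapply(seq_len(ncol(G)), function(m) {
        g <- G[, m]
        hweTest(sum(g == 2), sum(g == 1), sum(g == 0))
    }, numeric(1))
}

#' Variant quality control
#'
#' Keeps variants with empirical MAF >= `mafMin`, imputation info score >
#' `infoMin`, and Hardy-Weinberg p > `hwePMin` (chi-square test on
#' hard-called dosages). Removal counts per criterion are reported via
#' `message()` and attached as the `"qcLog"` attribute.
#'
#' @param g a [GenotypeMatrix-class].
#' @param mafMin minor-allele-frequency threshold (default 0.01).
#' @param infoMin imputation-quality threshold (default 0.7, exclusive).
#' @param hwePMin HWE p-value threshold (default 1e-7, exclusive).
#' @return The filtered [GenotypeMatrix-class].
#' @export
qcFilter <- function(g, mafMin = 0.01, infoMin = 0.7, hwePMin = 1e-7) {
    stopifnot(is(g, "GenotypeMatrix"))
    D <- dosages(g); v <- variantInfo(g)
    af <- colMeans(D) / 2
    maf <- pmin(af, 1 - af)
    hwe <- .hweFromDosages(D)
    failMaf <- maf < mafMin
    failInfo <- !(v$info > infoMin)
    failHwe <- !(hwe > hwePMin)
    keep <- !(failMaf | failInfo | failHwe)
    log <- c(n_in = ncol(D), fail_maf = sum(failMaf),
             fail_info = sum(failInfo), fail_hwe = sum(failHwe),
             n_out = sum(keep))
    message(sprintf(
        "qcFilter: %d -> %d variants (MAF %d, info %d, HWE %d removed)",
        log["n_in"], log["n_out"], log["fail_maf"], log["fail_info"],
        log["fail_hwe"]))
    if (!any(keep)) warning("qcFilter removed every variant")
    out <- genotypeMatrix(D[, keep, drop = FALSE],
                          v[keep, , drop = FALSE])
    attr(out, "qcLog") <- log
    out
}

#' Squared dosage correlation (linkage disequilibrium r^2)
#'
#' @param di,dj dosage vectors of equal length >= 2 with nonzero variance.
#' @return Squared Pearson correlation.
#' @export
ldR2 <- function(di, dj) {
    if (length(di) != length(dj) || length(di) < 2L)
        stop("dosage vectors must have equal length >= 2")
    if (stats::sd(di) == 0 || stats::sd(dj) == 0)
        stop("LD r^2 undefined for a zero-variance dosage vector")
    stats::cor(di, dj)^2
}

#' Greedy LD clumping of summary statistics
#'
#' Among variants with p < `pThresh`, the smallest-p unassigned variant is
#' repeatedly selected as an index; all unassigned variants on the same
#' chromosome within `windowKb` kilobases whose dosage r^2 with the index is
#' >= `r2Thresh` are clumped away. Ties on p are broken by smaller genomic
#' position. LD is computed in the target genotypes.
#'
#' @param ss a [SummaryStats-class].
#' @param g a [GenotypeMatrix-class] sharing variant ids with `ss`.
#' @param pThresh p-value threshold (default 0.01, exclusive).
#' @param r2Thresh r^2 threshold at-or-above which neighbours are removed
#'   (default 0.1).
#' @param windowKb half-window in kb (default 500): neighbours with
#'   `|pos - posIndex| <= windowKb * 1000` are in range.
#' @return Character vector of index-variant ids in selection order (empty
#'   if nothing passes `pThresh`).
#' @export
clumpVariants <- function(ss, g, pThresh = 0.01, r2Thresh = 0.1,
                          windowKb = 500) {
    stopifnot(is(ss, "SummaryStats"), is(g, "GenotypeMatrix"))
    v <- variantInfo(g)
    s <- sumStats(ss)
    s <- s[s$id %in% v$id, , drop = FALSE]
    m <- match(s$id, v$id)
    cand <- data.frame(id = s$id, p = s$p, chrom = v$chrom[m],
                       pos = v$pos[m], col = m, stringsAsFactors = FALSE)
    cand <- cand[cand$p < pThresh, , drop = FALSE]
    if (!nrow(cand)) return(character(0))
    ## deterministic greedy order: p, then position, then id
    cand <- cand[order(cand$p, cand$pos, cand$id), , drop = FALSE]
    D <- dosages(g)
    alive <- rep(TRUE, nrow(cand))
    idx <- character(0)
    for (i in seq_len(nrow(cand))) {
        if (!alive[i]) next
        idx <- c(idx, cand$id[i])
        alive[i] <- FALSE
        near <- which(alive & cand$chrom == cand$chrom[i] &
                          abs(cand$pos - cand$pos[i]) <= windowKb * 1000)
        if (!length(near)) next
        dIdx <- D[, cand$col[i]]
        if (stats::sd(dIdx) == 0) next
        for (j in near) {
            dj <- D[, cand$col[j]]
            if (stats::sd(dj) == 0) next
            if (stats::cor(dIdx, dj)^2 >= r2Thresh) alive[j] <- FALSE
        }
    }
    idx
}

#' Kinship-based relatedness pruning
#'
#' Builds the relatedness graph over pairs with kinship at or above
#' `threshold` and recursively removes the individual related to the
#' largest number of others (ties broken by lexicographically largest
#' subject id) until no related pair remains.
#'
#' @param pairs data.frame with columns `id1`, `id2`, `kinship`.
#' @param threshold kinship threshold (default 0.044).
#' @param subjects optional full subject-id pool; subjects never listed in
#'   `pairs` are always kept.
#' @return Character vector of kept subject ids (sorted).
#' @export
pruneRelatedness <- function(pairs, threshold = 0.044, subjects = NULL) {
    all <- sort(unique(c(subjects, pairs$id1, pairs$id2)))
    ek <- pairs$kinship >= threshold
    e1 <- pairs$id1[ek]; e2 <- pairs$id2[ek]
    removed <- character(0)
    repeat {
        live <- !(e1 %in% removed | e2 %in% removed)
        if (!any(live)) break
        deg <- table(c(e1[live], e2[live]))
        mx <- max(deg)
        pick <- max(names(deg)[deg == mx])  # lexicographically largest id
        removed <- c(removed, pick)
    }
    setdiff(all, removed)
}

#' Polygenic score from a weight table
#'
#' `score_s = sum_m alignedDosage_sm * w_m`, where the dosage is flipped to
#' `2 - d` when the weight's effect allele is the variant's other (ref)
#' allele. Weight rows for variants absent from the genotypes are skipped
#' (count reported); rows whose effect allele matches neither allele are
#' skipped with a warning. Missing dosages are mean-imputed per variant.
#'
#' @param g a [GenotypeMatrix-class].
#' @param weights data.frame with columns `id`, `effect_allele`, `weight`.
#' @param id label recorded as the weight-set id.
#' @return A [PGSVector-class].
#' @export
computePGS <- function(g, weights, id = "weights") {
    stopifnot(is(g, "GenotypeMatrix"),
              all(c("id", "effect_allele", "weight") %in% names(weights)))
    v <- variantInfo(g)
    D <- dosages(g)
    m <- match(weights$id, v$id)
    absent <- is.na(m)
    if (any(absent))
        message(sprintf("computePGS: %d weight variants absent from genotypes",
                        sum(absent)))
    w <- weights[!absent, , drop = FALSE]
    col <- m[!absent]
    isAlt <- w$effect_allele == v$alt[col]
    isRef <- w$effect_allele == v$ref[col]
    bad <- !(isAlt | isRef)
    if (any(bad)) {
        warning(sprintf("computePGS: %d variants with allele mismatch skipped",
                        sum(bad)))
        w <- w[!bad, , drop = FALSE]; col <- col[!bad]; isAlt <- isAlt[!bad]
    }
    score <- numeric(nrow(D)); names(score) <- rownames(D)
    if (nrow(w)) {
        Dm <- D[, col, drop = FALSE]
        if (anyNA(Dm)) {
            for (jj in seq_len(ncol(Dm))) {
                nas <- is.na(Dm[, jj])
                if (any(nas)) Dm[nas, jj] <- mean(Dm[!nas, jj])
            }
        }
        sgn <- ifelse(isAlt, 1, -1)
        ## flipped dosage (2 - d) folds into a sign and constant offset
        score <- as.numeric(Dm %*% (w$weight * sgn)) +
            sum(2 * w$weight[!isAlt])
        names(score) <- rownames(D)
    }
    new("PGSVector", score = score, weightSetId = id,
        nVariantsUsed = nrow(w))
}

#' Clumping-and-thresholding polygenic score family
#'
#' For each p-value threshold, the score uses the GWAS betas of (optionally
#' clumped) variants with p < threshold as weights. Clumping is performed
#' once at the loosest threshold; tighter thresholds subset its index list.
#'
#' @param ss a [SummaryStats-class].
#' @param g a [GenotypeMatrix-class].
#' @param pThresholds ascending numeric thresholds.
#' @param clumpFirst clump before thresholding (default TRUE).
#' @param r2Thresh,windowKb clumping parameters, see [clumpVariants()].
#' @return Named list of [PGSVector-class], one per threshold.
#' @export
pgsGrid <- function(ss, g, pThresholds = c(1e-4, 1e-3, 0.01, 0.05, 0.5, 1),
                    clumpFirst = TRUE, r2Thresh = 0.1, windowKb = 500) {
    stopifnot(!is.unsorted(pThresholds))
    s <- sumStats(ss)
    useIds <- if (clumpFirst) {
        clumpVariants(ss, g, pThresh = max(pThresholds) + 1e-300,
                      r2Thresh = r2Thresh, windowKb = windowKb)
    } else s$id
    out <- list()
    for (th in pThresholds) {
        ids <- intersect(useIds, s$id[s$p < th])
        nm <- paste0("p", format(th))
        if (!length(ids)) {
            warning(sprintf("pgsGrid: no variants at threshold %g", th))
            sc <- numeric(nrow(dosages(g)))
            names(sc) <- rownames(dosages(g))
            out[[nm]] <- new("PGSVector", score = sc, weightSetId = nm,
                             nVariantsUsed = 0L)
        } else {
            ww <- s[match(ids, s$id), c("id", "effect_allele", "beta")]
            names(ww)[3] <- "weight"
            out[[nm]] <- computePGS(g, ww, id = nm)
        }
    }
    out
}

#' Select the polygenic score maximizing its top IDP association
#'
#' Every candidate score is regressed against every imaging-derived
#' phenotype with covariate adjustment; the candidate with the largest
#' max |t| over IDPs wins.
#'
#' @param family named list of [PGSVector-class] candidates.
#' @param idps subject x IDP numeric matrix.
#' @param covariates covariate data.frame (same subject order).
#' @return List with `best` (name), `pgs` (the winning [PGSVector-class]),
#'   and `tGrid` (candidate x IDP t-statistics).
#' @export
optimizePGS <- function(family, idps, covariates) {
    stopifnot(length(family) >= 1L, ncol(idps) >= 1L)
    X <- cbind(intercept = 1, as.matrix(covariates))
    qrX <- qr(X)
    Q <- qr.Q(qrX)
    RY <- idps - Q %*% crossprod(Q, idps)
    df <- nrow(idps) - qrX$rank - 1L
    tGrid <- matrix(NA_real_, length(family), ncol(idps),
                    dimnames = list(names(family), colnames(idps)))
    for (i in seq_along(family)) {
        x <- pgsScores(family[[i]])
        rx <- x - as.numeric(Q %*% crossprod(Q, x))
        sxx <- sum(rx^2)
        if (sxx / max(sum(x^2), .Machine$double.eps) < 1e-12) next
        beta <- as.numeric(crossprod(rx, RY)) / sxx
        sse <- pmax(colSums(RY^2) - beta^2 * sxx, 0)
        se <- sqrt(sse / df / sxx)
        tGrid[i, ] <- ifelse(se > 0, beta / se, sign(beta) * Inf)
    }
    top <- apply(abs(tGrid), 1, max, na.rm = TRUE)
    best <- names(family)[which.max(top)]
    list(best = best, pgs = family[[best]], tGrid = tGrid)
}
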