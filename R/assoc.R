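#' Build a GLM design matrix from covariates
#'
#' The default design is an intercept plus every covariate-table column.
#' Optional adjustments mirror the standard secondary models: a head-size
#' column (volumetric data), a global-mean apparent-fiber-density column
#' (fixel data), and extra covariates (e.g. cognitive scores). The returned
#' spec also records whether element values should be log-transformed
#' before fitting (allometry-aware analysis of Jacobian determinants).
#'
#' @param covariates data.frame of base covariates, complete for all
#'   subjects.
#' @param headSize optional numeric per-subject head-size measure.
#' @param globalAfd optional numeric per-subject global mean AFD.
#' @param extra optional data.frame of additional covariates.
#' @param logTransform log-transform element values before fitting.
#' @return List of class `glmDesign`: `X` (design matrix including
#'   intercept), `logTransform`, `description`.
#' @export
buildDesign <- function(covariates, headSize = NULL, globalAfd = NULL,
                        extra = NULL, logTransform = FALSE) {
    cv <- as.data.frame(covariates)
    bad <- rownames(cv)[!stats::complete.cases(cv)]
    if (length(bad))
        stop("missing covariate values for subjects: ",
             paste(bad, collapse = ", "))
    X <- cbind(intercept = 1, as.matrix(cv))
    parts <- "base"
    if (!is.null(headSize)) {
        X <- cbind(X, head_size = as.numeric(headSize))
        parts <- c(parts, "head_size")
    }
    if (!is.null(globalAfd)) {
        X <- cbind(X, global_afd = as.numeric(globalAfd))
        parts <- c(parts, "global_afd")
    }
    if (!is.null(extra)) {
        ex <- as.data.frame(extra)
        if (any(!stats::complete.cases(ex)))
            stop("missing values in extra covariates")
        X <- cbind(X, as.matrix(ex))
        parts <- c(parts, colnames(ex))
    }
    if (logTransform) parts <- c(parts, "log_transform")
    structure(list(X = X, logTransform = logTransform,
                   description = paste(parts, collapse = "+")),
              class = "glmDesign")
}

## orthonormal basis of the design column space + projection helpers
.designQ <- function(design) {
    qrX <- qr(design$X)
    list(Q = qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE], rank = qrX$rank)
}

.residualize <- function(Q, M) M - Q %*% crossprod(Q, M)

## vectorized OLS t for one predictor (residualized) against residualized Y
.tFromResiduals <- function(rx, RY, df) {
    sxx <- sum(rx^2)
    beta <- as.numeric(crossprod(rx, RY)) / sxx
    sse <- pmax(colSums(RY^2) - beta^2 * sxx, 0)
    se <- sqrt(sse / df / sxx)
    t <- ifelse(se > 0, beta / se, 0)
    ## degenerate elements (zero residual variance) get t = 0
    t[colSums(RY^2) < .Machine$double.eps * nrow(RY)] <- 0
    list(t = t, beta = beta)
}

#' Mass-univariate GLM of brain elements on one predictor
#'
#' Per element, ordinary least squares of the element value on
#' `[predictor | design]`, computed by residualizing both the predictor and
#' the values on the design (Frisch-Waugh): the t-statistic equals the
#' full-design OLS t. Elements with zero variance after residualization get
#' t = 0 (their count is reported).
#'
#' @param maps an [ElementMaps-class].
#' @param x numeric predictor vector (a polygenic score or allele dosage).
#' @param design a `glmDesign` from [buildDesign()].
#' @param predictorId row label for the result.
#' @return A [TStatMatrix-class] with one row: t, beta, and partial r^2
#'   (`t^2 / (t^2 + df)`).
#' @export
fitGLM <- function(maps, x, design, predictorId = "predictor") {
    stopifnot(is(maps, "ElementMaps"), length(x) == nrow(mapValues(maps)))
    Y <- mapValues(maps)
    if (design$logTransform) Y <- log(Y)
    dq <- .designQ(design)
    rx <- as.numeric(.residualize(dq$Q, matrix(x, ncol = 1)))
    if (sum(rx^2) / max(sum(x^2), .Machine$double.eps) < 1e-10)
        stop("predictor collinear with covariates")
    RY <- .residualize(dq$Q, Y)
    df <- nrow(Y) - dq$rank - 1L
    if (df <= 0) stop("no residual degrees of freedom")
    ft <- .tFromResiduals(rx, RY, df)
    nDegen <- sum(colSums(RY^2) < .Machine$double.eps * nrow(RY))
    if (nDegen) message(sprintf("fitGLM: %d degenerate elements (t set to 0)",
                                nDegen))
    tm <- matrix(ft$t, 1, ncol(Y),
                 dimnames = list(predictorId, colnames(Y)))
    bm <- matrix(ft$beta, 1, ncol(Y),
                 dimnames = dimnames(tm))
    new("TStatMatrix", t = tm, beta = bm,
        partialR2 = tm^2 / (tm^2 + df), df = as.numeric(df),
        model = design$description)
}

#' Per-variant brain-wide t-maps
#'
#' One covariate-adjusted GLM row per variant, predictor = dosage of the
#' disposing (effect) allele: when summary statistics are supplied and a
#' variant's effect allele is the genotype ref allele, its dosage is
#' flipped to `2 - d` so that t is reported with respect to increasing
#' disposing-allele dosage. Monomorphic variants yield a flagged NA row.
#'
#' @param g a [GenotypeMatrix-class].
#' @param variantIds variants to map (default: all in `g`).
#' @param maps an [ElementMaps-class].
#' @param design a `glmDesign`.
#' @param ss optional [SummaryStats-class] supplying effect alleles.
#' @return A [TStatMatrix-class], one row per variant.
#' @export
variantTMaps <- function(g, variantIds = variantInfo(g)$id, maps, design,
                         ss = NULL) {
    stopifnot(is(g, "GenotypeMatrix"), is(maps, "ElementMaps"))
    v <- variantInfo(g)
    miss <- setdiff(variantIds, v$id)
    if (length(miss)) stop("variants absent from genotypes: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    Y <- mapValues(maps)
    if (design$logTransform) Y <- log(Y)
    dq <- .designQ(design)
    RY <- .residualize(dq$Q, Y)
    df <- nrow(Y) - dq$rank - 1L
    if (df <= 0) stop("no residual degrees of freedom")
    cols <- match(variantIds, v$id)
    D <- dosages(g)[, cols, drop = FALSE]
    if (!is.null(ss)) {
        s <- sumStats(ss)
        sm <- match(variantIds, s$id)
        flip <- !is.na(sm) & s$effect_allele[sm] == v$ref[cols]
        if (any(flip)) D[, flip] <- 2 - D[, flip]
    }
    RX <- .residualize(dq$Q, D)
    sxx <- colSums(RX^2)
    mono <- apply(D, 2, stats::sd) == 0
    tM <- matrix(NA_real_, length(variantIds), ncol(Y),
                 dimnames = list(variantIds, colnames(Y)))
    bM <- tM
    ok <- which(!mono & sxx > 0)
    if (length(ok)) {
        B <- crossprod(RX[, ok, drop = FALSE], RY) / sxx[ok]  # v x e betas
        ssY <- colSums(RY^2)
        sse <- pmax(rep(ssY, each = length(ok)) - B^2 * sxx[ok], 0)
        se <- sqrt(sse / df / sxx[ok])
        tt <- ifelse(se > 0, B / se, 0)
        degenE <- ssY < .Machine$double.eps * nrow(RY)
        tt[, degenE] <- 0
        tM[ok, ] <- tt
        bM[ok, ] <- B
    }
    if (any(mono))
        message(sprintf("variantTMaps: %d monomorphic variants flagged NA",
                        sum(mono)))
    new("TStatMatrix", t = tM, beta = bM,
        partialR2 = tM^2 / (tM^2 + df), df = as.numeric(df),
        model = design$description)
}

#' Max-statistic permutation inference for brain-wide FWE control
#'
#' Freedman-Lane-style scheme: the element values and the predictor are
#' residualized on the nuisance design; each permutation shuffles the
#' residualized predictor (re-residualizing it on the design) and records
#' the maximum statistic over elements. The FWE-corrected p-value of an
#' element is `(1 + #permutation maxima >= observed) / (nPerm + 1)`; the +1
#' (inclusion of the unpermuted statistic) guarantees validity. No cluster
#' enhancement is applied.
#'
#' @param maps an [ElementMaps-class].
#' @param x numeric predictor.
#' @param design a `glmDesign`.
#' @param nPerm number of permutations (>= 100; default 5000).
#' @param seed permutation seed.
#' @param tail `"two"` (|t|, default), `"right"` (t) or `"left"` (-t).
#' @param chunk permutations processed per block (memory control).
#' @return An [FweResult-class].
#' @export
permutationFWE <- function(maps, x, design, nPerm = 5000L, seed = 1L,
                           tail = c("two", "right", "left"), chunk = 500L) {
    tail <- match.arg(tail)
    stopifnot(nPerm >= 100L)
    Y <- mapValues(maps)
    if (design$logTransform) Y <- log(Y)
    n <- nrow(Y)
    if (n < 8L) warning("very few subjects: permutation distribution is coarse")
    dq <- .designQ(design)
    rx <- as.numeric(.residualize(dq$Q, matrix(x, ncol = 1)))
    if (sum(rx^2) / max(sum(x^2), .Machine$double.eps) < 1e-10)
        stop("predictor collinear with covariates")
    RY <- .residualize(dq$Q, Y)
    df <- n - dq$rank - 1L
    stat <- function(tv) switch(tail, two = abs(tv), right = tv, left = -tv)
    tObs <- .tFromResiduals(rx, RY, df)$t
    sObs <- stat(tObs)
    ssY <- colSums(RY^2)
    degen <- ssY < .Machine$double.eps * n
    nullMax <- numeric(nPerm)
    done <- 0L
    .withSeed(childSeed(seed, "permutation-fwe"), {
        while (done < nPerm) {
            nb <- min(chunk, nPerm - done)
            P <- vapply(seq_len(nb), function(i) rx[sample.int(n)],
                        numeric(n))
            P <- .residualize(dq$Q, P)  # re-residualize permuted predictor
            sxx <- colSums(P^2)
            B <- crossprod(P, RY) / sxx          # perm x element betas
            sse <- pmax(rep(ssY, each = nb) - B^2 * sxx, 0)
            se <- sqrt(sse / df / sxx)
            Tp <- ifelse(se > 0, B / se, 0)
            if (any(degen)) Tp[, degen] <- 0
            nullMax[done + seq_len(nb)] <-
                apply(stat(Tp), 1, max)
            done <- done + nb
        }
    })
    cnt <- vapply(sObs, function(s) sum(nullMax >= s), numeric(1))
    p <- (1 + cnt) / (nPerm + 1)
    p[degen] <- 1
    names(p) <- colnames(Y)
    new("FweResult", p = p, tObs = tObs, nullMax = nullMax,
        nPerm = as.integer(nPerm), seed = as.integer(seed), tail = tail)
}

#' Principal-component imaging-derived phenotypes
#'
#' Subject scores of the top principal components of the subject x element
#' matrix (centred per element), computed at each requested dimensionality
#' and concatenated with provenance labels (`d<dim>.PC<j>`).
#'
#' @param maps an [ElementMaps-class].
#' @param nComponents integer vector of dimensionalities.
#' @return Numeric matrix, subjects x total IDPs.
#' @export
idpExtract <- function(maps, nComponents = c(2L, 5L)) {
    Y <- mapValues(maps)
    dmax <- max(nComponents)
    if (dmax > min(nrow(Y), ncol(Y)))
        stop("requested dimension exceeds min(nSubjects, nElements)")
    if (nrow(Y) <= dmax)
        stop("need more subjects than the largest requested dimension")
    Yc <- scale(Y, center = TRUE, scale = FALSE)
    sv <- svd(Yc, nu = dmax, nv = 0)
    scores <- sv$u %*% diag(sv$d[seq_len(dmax)], dmax)
    out <- do.call(cbind, lapply(nComponents, function(d) {
        m <- scores[, seq_len(d), drop = FALSE]
        colnames(m) <- sprintf("d%d.PC%d", d, seq_len(d))
        m
    }))
    rownames(out) <- rownames(Y)
    out
}
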