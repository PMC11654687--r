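test_that("HWE chi-square matches hand values and handles degeneracy", {
    expect_equal(hweTest(25, 50, 25), 1.0)              # exact HWE
    ## no heterozygotes at p = 0.5: chi2 = 100 against expected 25/50/25
    expect_equal(hweTest(50, 0, 50),
                 pchisq(100, df = 1, lower.tail = FALSE), tolerance = 1e-12)
    expect_equal(hweTest(50, 0, 50), 1.523971e-23, tolerance = 1e-6)
    expect_equal(hweTest(100, 0, 0), 1.0)               # monomorphic
    expect_error(hweTest(-1, 5, 5), "nonnegative")
})

test_that("HWE agrees with an independent chi-square oracle on random triples", {
    set.seed(42)
    for (i in 1:200) {
        n <- sample(10:500, 3)
        pA <- (2 * n[1] + n[2]) / (2 * sum(n))
        pOracle <- if (pA <= 0 || pA >= 1) 1.0 else {
            e <- sum(n) * c(pA^2, 2 * pA * (1 - pA), (1 - pA)^2)
            pchisq(sum((n - e)^2 / e), 1, lower.tail = FALSE)
        }
        expect_equal(hweTest(n[1], n[2], n[3]), pOracle, tolerance = 1e-10)
    }
})

test_that("qcFilter removes exactly the violating variants, idempotently", {
    set.seed(7)
    n <- 400L
    ok1 <- rbinom(n, 2, 0.3); ok2 <- rbinom(n, 2, 0.4)
    rare <- rbinom(n, 2, 0.004)                       # fails MAF
    hweBad <- rep(c(0, 2), length.out = n)            # no hets: fails HWE
    lowInfo <- rbinom(n, 2, 0.3)                      # fails info
    D <- cbind(v_ok1 = ok1, v_rare = rare, v_ok2 = ok2,
               v_hwe = hweBad, v_info = lowInfo)
    g <- toyGenotypes(D)
    g@variants$info <- c(0.99, 0.99, 0.99, 0.99, 0.5)
    suppressMessages(out <- qcFilter(g))
    expect_identical(variantInfo(out)$id, c("v_ok1", "v_ok2"))
    log <- attr(out, "qcLog")
    expect_equal(unname(log[c("fail_maf", "fail_info", "fail_hwe")]),
                 c(1, 1, 1))
    ## nothing removed when everything passes; applying twice = once
    suppressMessages(out2 <- qcFilter(out))
    expect_identical(dosages(out2), dosages(out))
})

test_that("ldR2 matches the correlation oracle and flags degenerate input", {
    expect_equal(ldR2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1.0)
    expect_equal(ldR2(c(0, 1, 2, 0), c(2, 1, 0, 2)), 1.0)  # perfect negative
    set.seed(1)
    for (i in 1:20) {
        a <- rbinom(30, 2, 0.4); b <- rbinom(30, 2, 0.4)
        if (sd(a) == 0 || sd(b) == 0) next
        expect_equal(ldR2(a, b), cor(a, b)^2, tolerance = 1e-12)
    }
    expect_error(ldR2(rep(1, 5), c(0, 1, 2, 1, 0)), "zero-variance")
})

test_that("clumping follows the greedy hand-execution", {
    set.seed(3)
    base <- rbinom(80, 2, 0.5)
    corr <- ifelse(rbinom(80, 1, 0.9) == 1, base, rbinom(80, 2, 0.5))
    indep <- rbinom(80, 2, 0.5)
    ## three variants in one window: p = 1e-5, 1e-4, 0.5; r2(1,2) high
    D <- cbind(v1 = base, v2 = corr, v3 = indep)
    g <- toyGenotypes(D, pos = c(10000L, 20000L, 30000L))
    ss <- toySumstats(colnames(D), p = c(1e-5, 1e-4, 0.5))
    expect_identical(clumpVariants(ss, g), "v1")

    ## two unlinked significant variants are both indices
    D2 <- cbind(a = rbinom(80, 2, 0.5), b = rbinom(80, 2, 0.5))
    g2 <- toyGenotypes(D2, pos = c(10000L, 20000L))
    ss2 <- toySumstats(colnames(D2), p = c(1e-4, 1e-3))
    expect_setequal(clumpVariants(ss2, g2), c("a", "b"))

    ## r2 = 1 but 600 kb apart: window rule keeps both
    D3 <- cbind(x = base, y = base)
    g3 <- toyGenotypes(D3, pos = c(10000L, 610000L))
    ss3 <- toySumstats(colnames(D3), p = c(1e-5, 1e-4))
    expect_setequal(clumpVariants(ss3, g3), c("x", "y"))
    ## ... and different chromosomes never clump each other
    g4 <- toyGenotypes(D3, chrom = c(1L, 2L), pos = c(10000L, 20000L))
    expect_setequal(clumpVariants(ss3, g4), c("x", "y"))

    ## nothing passes the p threshold: empty, not an error
    expect_identical(clumpVariants(toySumstats(colnames(D2), p = c(0.5, 0.9)),
                                   g2), character(0))
})

test_that("clumping is order-independent and idempotent", {
    set.seed(11)
    cfg <- simConfig(nSubjects = 150L, nVariants = 40L, ldBlockSize = 4L,
                     ldDecay = 0.95, seed = 13L)
    g <- genGenotypes(cfg)
    p <- runif(40)^3
    ss <- toySumstats(variantInfo(g)$id, p = p)
    idx <- clumpVariants(ss, g, pThresh = 0.5)
    ## shuffle summary-stat rows: same indices
    perm <- sample(40)
    ssPerm <- summaryStats(sumStats(ss)[perm, ])
    expect_identical(sort(clumpVariants(ssPerm, g, pThresh = 0.5)), sort(idx))
    ## clumping the already-clumped set changes nothing
    keep <- match(idx, variantInfo(g)$id)
    g2 <- genotypeMatrix(dosages(g)[, keep, drop = FALSE],
                         variantInfo(g)[keep, ])
    ss2 <- summaryStats(sumStats(ss)[match(idx, sumStats(ss)$id), ])
    expect_identical(sort(clumpVariants(ss2, g2, pThresh = 0.5)), sort(idx))
})

test_that("relatedness pruning removes hubs and leaves no related pair", {
    ## star: hub H related to 4 leaves -> H removed, leaves kept
    star <- data.frame(id1 = "H", id2 = c("L1", "L2", "L3", "L4"),
                       kinship = 0.25)
    expect_setequal(pruneRelatedness(star), c("L1", "L2", "L3", "L4"))
    ## empty table keeps everyone
    expect_setequal(pruneRelatedness(star[0, ], subjects = c("a", "b")),
                    c("a", "b"))
    ## chain a-b-c-d: removing max-degree (tie -> largest id, "c") then "b"
    chain <- data.frame(id1 = c("a", "b", "c"), id2 = c("b", "c", "d"),
                        kinship = 0.25)
    expect_setequal(pruneRelatedness(chain), c("a", "d"))
    ## clique of 3 leaves one survivor (smallest id by tie-break)
    clique <- data.frame(id1 = c("x", "x", "y"), id2 = c("y", "z", "z"),
                         kinship = 0.0625)
    expect_identical(pruneRelatedness(clique), "x")
    ## sub-threshold pairs are not edges
    sub <- data.frame(id1 = "p", id2 = "q", kinship = 0.03)
    expect_setequal(pruneRelatedness(sub), c("p", "q"))
    ## postcondition on random graphs: kept set is edge-free, idempotent
    set.seed(5)
    for (r in 1:10) {
        k <- genKinship(30L, 15L, seed = r)
        kept <- pruneRelatedness(k)
        rel <- k[k$kinship >= 0.044, ]
        expect_equal(sum(rel$id1 %in% kept & rel$id2 %in% kept), 0L)
        expect_identical(pruneRelatedness(k[k$id1 %in% kept &
                                            k$id2 %in% kept, ],
                                          subjects = kept), kept)
    }
})

test_that("computePGS aligns alleles and matches hand computation", {
    D <- rbind(S1 = c(0, 1, 2), S2 = c(2, 0, 1), S3 = c(1, 2, 0))
    colnames(D) <- c("v1", "v2", "v3")
    g <- toyGenotypes(D)  # ref A, alt G
    ## all-zero weights
    w0 <- data.frame(id = colnames(D), effect_allele = "G", weight = 0)
    expect_true(all(pgsScores(computePGS(g, w0)) == 0))
    ## single variant, weight 1, effect allele = alt: score = dosage
    w1 <- data.frame(id = "v2", effect_allele = "G", weight = 1)
    expect_equal(unname(pgsScores(computePGS(g, w1))), D[, "v2"],
                 ignore_attr = TRUE)
    ## one allele flip: v3 effect allele = ref A -> aligned dosage 2 - d
    w <- data.frame(id = c("v1", "v2", "v3"),
                    effect_allele = c("G", "G", "A"),
                    weight = c(0.5, -1, 2))
    hand <- D[, "v1"] * 0.5 + D[, "v2"] * -1 + (2 - D[, "v3"]) * 2
    expect_equal(unname(pgsScores(computePGS(g, w))), unname(hand))
    ## strand-consistent relabeling with matching dosage flip: same score
    gFlip <- toyGenotypes(2 - D)
    gFlip@variants$ref <- "G"; gFlip@variants$alt <- "A"
    expect_equal(pgsScores(computePGS(gFlip, w)), pgsScores(computePGS(g, w)))
    ## allele mismatch -> skipped with warning; absent variant -> message
    wBad <- data.frame(id = "v1", effect_allele = "T", weight = 1)
    expect_warning(computePGS(g, wBad), "allele mismatch")
    wAbsent <- data.frame(id = "nope", effect_allele = "G", weight = 1)
    expect_message(computePGS(g, wAbsent), "absent")
})

test_that("pgsGrid thresholds nest and the full score equals computePGS", {
    cfg <- simConfig(nSubjects = 120L, nVariants = 60L, ldBlockSize = 3L,
                     ldDecay = 0.5, seed = 17L)
    g <- genGenotypes(cfg)
    tr <- genTruth(cfg)
    ss <- genSumstats(g, tr, cfg, nDiscovery = 2000L)
    fam <- suppressWarnings(
        pgsGrid(ss, g, pThresholds = c(1e-3, 0.05, 1), clumpFirst = FALSE))
    counts <- vapply(fam, function(p) p@nVariantsUsed, integer(1))
    expect_true(all(diff(counts) >= 0))
    s <- sumStats(ss)
    wFull <- data.frame(id = s$id, effect_allele = s$effect_allele,
                        weight = s$beta)
    expect_equal(pgsScores(fam[["p1"]]), pgsScores(computePGS(g, wFull)))
})

test_that("planted-architecture PGS correlates with the liability", {
    cfg <- simConfig(nSubjects = 400L, nVariants = 100L, ldBlockSize = 2L,
                     ldDecay = 0.3, causalSd = 0.25, seed = 23L)
    g <- genGenotypes(cfg)
    tr <- genTruth(cfg)
    ss <- genSumstats(g, tr, cfg, nDiscovery = 8000L)
    fam <- suppressWarnings(pgsGrid(ss, g, pThresholds = c(1e-3, 0.01, 0.1)))
    liability <- as.numeric(scale(dosages(g), scale = FALSE) %*%
                                tr@causalWeights)
    rs <- vapply(fam, function(p) cor(pgsScores(p), liability), numeric(1))
    ## r > 0 at 3 sigma (Fisher bound ~ 3/sqrt(n))
    expect_gt(max(rs), 3 / sqrt(cfg@nSubjects))
})

test_that("optimizePGS picks the top-association candidate", {
    set.seed(31)
    n <- 80L
    cv <- randomCovariates(n, 3L)
    idps <- matrix(rnorm(n * 4L), n, 4L,
                   dimnames = list(NULL, paste0("idp", 1:4)))
    mk <- function(x, id) new("PGSVector", score = setNames(x, rownames(cv)),
                              weightSetId = id, nVariantsUsed = 10L)
    ## single candidate wins by default
    only <- list(a = mk(rnorm(n), "a"))
    expect_identical(optimizePGS(only, idps, cv)$best, "a")
    ## a candidate equal to a noiseless IDP dominates
    fam <- list(noise = mk(rnorm(n), "noise"),
                perfect = mk(idps[, 2], "perfect"))
    sel <- optimizePGS(fam, idps, cv)
    expect_identical(sel$best, "perfect")
    expect_equal(dim(sel$tGrid), c(2L, 4L))
})
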