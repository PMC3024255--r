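# Correlation-network preservation statistics, eigennode separability,
# and module quality.

test_that("with identical data all correlation statistics hit their
           self-comparison limits", {
    st <- makeCorStudy(seed = 3)
    d <- corDensityStats(st$Xref, st$Xref, st$labels)
    cc <- corConnectivityStats(st$Xref, st$Xref, st$labels)
    # sign(c) * c = |c|: sign-aware density equals mean absolute correlation
    C <- computeCorrelation(st$Xref)
    for (q in d$module) {
        idx <- names(st$labels)[st$labels == q]
        expect_equal(d$meanSignAwareCorDat[d$module == q],
                     mean(abs(vectorizeUpper(C[idx, idx]))),
                     tolerance = 1e-12)
    }
    expect_equal(cc$cor.cor, rep(1, 2), tolerance = 1e-12)
    expect_equal(cc$cor.kME, rep(1, 2), tolerance = 1e-12)
    expect_equal(cc$cor.kMEall, rep(1, 2), tolerance = 1e-12)

    # a module of identical test profiles explains all its variance
    z <- rnorm(40)
    Xconst <- st$Xtest
    idx1 <- which(st$labels == "M01")
    for (i in idx1) Xconst[, i] <- z
    dc <- corDensityStats(st$Xref, Xconst, st$labels)
    expect_equal(dc$propVarExplained[dc$module == "M01"], 1,
                 tolerance = 1e-10)
})

test_that("correlation statistics match explicit-assembly oracles on
           random paired data", {
    st <- makeCorStudy(seed = 11, preserveAll = FALSE)
    d <- corDensityStats(st$Xref, st$Xtest, st$labels)
    cc <- corConnectivityStats(st$Xref, st$Xtest, st$labels)
    Cr <- oracleCorMatrix(st$Xref)
    Ct <- oracleCorMatrix(st$Xtest)
    dimnames(Cr) <- dimnames(Ct) <- list(names(st$labels), names(st$labels))
    for (q in c("M01", "M02")) {
        idx <- which(st$labels == q)
        ur <- vectorizeUpper(Cr[idx, idx])
        ut <- vectorizeUpper(Ct[idx, idx])
        expect_equal(d$meanSignAwareCorDat[d$module == q],
                     mean(sign(ur) * ut), tolerance = 1e-10)
        expect_equal(cc$cor.cor[cc$module == q], oracleCorPair(ur, ut),
                     tolerance = 1e-10)
        # kME oracle: correlations with independently recomputed eigennodes
        er <- moduleEigennode(st$Xref[, idx])$eigennode
        et <- moduleEigennode(st$Xtest[, idx])$eigennode
        kr <- apply(st$Xref, 2, function(x) oracleCorPair(x, er))
        kt <- apply(st$Xtest, 2, function(x) oracleCorPair(x, et))
        expect_equal(d$propVarExplained[d$module == q], mean(kt[idx]^2),
                     tolerance = 1e-10)
        expect_equal(d$meanSignAwareKME[d$module == q],
                     mean(sign(kr[idx]) * kt[idx]), tolerance = 1e-10)
        expect_equal(cc$cor.kME[cc$module == q],
                     oracleCorPair(kr[idx], kt[idx]), tolerance = 1e-10)
        expect_equal(cc$cor.kMEall[cc$module == q], oracleCorPair(kr, kt),
                     tolerance = 1e-10)
    }
})

test_that("null test data give sign-aware statistics near zero across
           replicates", {
    reps <- 30
    vals <- sapply(seq_len(reps), function(r) {
        st <- makeCorStudy(m = 30, sizes = c(8, 8), seed = 100 + r,
                           preserveAll = FALSE)
        d <- corDensityStats(st$Xref, st$Xtest, st$labels)
        k <- corConnectivityStats(st$Xref, st$Xtest, st$labels)
        c(d$meanSignAwareCorDat[1], k$cor.kME[1])
    })
    for (i in 1:2) {
        mcse <- sd(vals[i, ]) / sqrt(reps)
        expect_lt(abs(mean(vals[i, ])), 3 * mcse + 1e-8)
    }
})

test_that("eigennode separability: shared seed 0, orthogonal seeds 1,
           random data matches the recomputed-eigennode oracle", {
    m <- 24
    z <- rnorm(m)
    # noiseless modules from the same seed profile
    ids <- paste0("g", 1:8)
    lab <- makeLabels(c(4, 4), ids, greyRest = FALSE)
    Xsame <- sapply(1:8, function(i) z * (1 + 0.5 * (i %% 3)))
    colnames(Xsame) <- ids
    s <- eigennodeSeparability(Xsame, lab)
    expect_equal(unname(s$perModule), c(0, 0), tolerance = 1e-10)

    # exactly orthogonal seed profiles
    z2 <- residuals(lm(rnorm(m) ~ z))
    Xorth <- cbind(sapply(1:4, function(i) z * i),
                   sapply(1:4, function(i) z2 * i))
    colnames(Xorth) <- ids
    so <- eigennodeSeparability(Xorth, lab)
    expect_equal(unname(so$perModule), c(1, 1), tolerance = 1e-10)

    # random data: 1 - |cor| (unsigned) / 1 - cor (signed) of the
    # independently recomputed eigennodes
    X <- makeExpr(30, 9, seed = 6)
    lab3 <- makeLabels(c(3, 3, 3), colnames(X), greyRest = FALSE)
    e <- lapply(c("M01", "M02", "M03"), function(q)
        moduleEigennode(X[, lab3 == q])$eigennode)
    cc12 <- oracleCorPair(e[[1]], e[[2]])
    cc13 <- oracleCorPair(e[[1]], e[[3]])
    su <- eigennodeSeparability(X, lab3, networkType = "unsigned")
    ss <- eigennodeSeparability(X, lab3, networkType = "signed")
    expect_equal(unname(su$pairwise["M01", "M02"]), 1 - abs(cc12),
                 tolerance = 1e-10)
    expect_equal(unname(ss$pairwise["M01", "M03"]), 1 - cc13,
                 tolerance = 1e-10)
    expect_equal(unname(su$perModule["M01"]),
                 min(1 - abs(cc12), 1 - abs(cc13)), tolerance = 1e-10)
})

test_that("quality statistics: tight modules score high, identical
           profiles give unit density at beta = 1", {
    st <- makeCorStudy(m = 50, sizes = c(12, 12), minCor = .7, maxCor = .9,
                       seed = 21)
    q <- qualityStats(st$Xref, st$labels)
    expect_true(all(q$quality.propVarExplained > 0.5))

    z <- rnorm(30)
    Xid <- sapply(1:6, function(i) z)
    colnames(Xid) <- paste0("g", 1:6)
    qi <- qualityStats(Xid + 0, makeLabels(c(3, 3), colnames(Xid)),
                       power = 1)
    expect_equal(qi$quality.meanAdj, c(1, 1), tolerance = 1e-10)
})

test_that("statistics are invariant under negating all measurements in
           both data sets simultaneously", {
    st <- makeCorStudy(seed = 9)
    d1 <- corDensityStats(st$Xref, st$Xtest, st$labels)
    d2 <- corDensityStats(-st$Xref, -st$Xtest, st$labels)
    k1 <- corConnectivityStats(st$Xref, st$Xtest, st$labels)
    k2 <- corConnectivityStats(-st$Xref, -st$Xtest, st$labels)
    expect_equal(d1, d2, tolerance = 1e-10)
    expect_equal(k1, k2, tolerance = 1e-10)
})
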