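# Synthetic-data generator: scenario conformance, preservation signal,
# determinism, and the 4-point grading harness.

test_that("scenario defaults conform: weak 20x200, strong 10 modules
           100-400, pathway size bounds attained", {
    weak <- scenarioSpec("weak")
    expect_equal(weak$nModules, 20L)
    expect_equal(weak$moduleSizes, rep(200L, 20L))
    strong <- scenarioSpec("strong")
    expect_equal(length(strong$moduleSizes), 10L)
    expect_equal(range(strong$moduleSizes), c(100L, 400L))
    expect_equal(strong$minCor, 0.6)
    expect_equal(strong$maxCor, 0.95)
    ps <- scenarioSpec("pathway_small")
    expect_equal(range(ps$moduleSizes), c(25L, 100L))
    pl <- scenarioSpec("pathway_large")
    expect_equal(range(pl$moduleSizes), c(100L, 500L))
    expect_error(scenarioSpec("strong", moduleSizes = c(2, 50)), "at least 3")
})

test_that("simulated studies deliver the promised module structure and
           are bit-identical under a fixed seed", {
    sim <- simulateScenario("weak", seed = 5)
    tr <- moduleTruth(sim)
    expect_equal(nrow(tr), 20L)
    expect_true(all(tr$size == 200L))
    expect_equal(sum(tr$preserved), 10L)
    sizes <- table(moduleLabels(sim))
    expect_true(all(sizes[tr$module] == 200L))
    # grey nodes are 25% of proper nodes
    expect_equal(unname(sizes["grey"]), round(0.25 * 20 * 200))

    ps <- simulateScenario("pathway_small", seed = 2)
    expect_equal(min(moduleTruth(ps)$size), 25L)
    expect_equal(max(moduleTruth(ps)$size), 100L)

    sim2 <- simulateScenario("weak", seed = 5)
    expect_identical(refExpression(sim), refExpression(sim2))
    expect_identical(testExpression(sim), testExpression(sim2))
    sim3 <- simulateScenario("weak", seed = 6)
    expect_false(identical(refExpression(sim), refExpression(sim3)))
})

test_that("preserved modules reproduce their kME structure at vanishing
           noise", {
    sim <- simulateScenario("strong", nModules = 3,
                            moduleSizes = c(30, 30, 30), nSamples = 60,
                            minCor = 0.99, maxCor = 0.99, seed = 9)
    lab <- moduleLabels(sim)
    for (q in c("M01")) {
        idx <- which(lab == q)
        er <- moduleEigennode(refExpression(sim)[, idx])$eigennode
        et <- moduleEigennode(testExpression(sim)[, idx])$eigennode
        kr <- moduleMembership(refExpression(sim)[, idx], er)
        kt <- moduleMembership(testExpression(sim)[, idx], et)
        # at membership correlation 0.99 the kME structure reproduces
        # almost exactly in the preserved test module
        expect_gt(mean(kr), 0.95)
        expect_gt(mean(kt), 0.95)
        expect_lt(mean(abs(kr - kt)), 0.05)
    }
})

test_that("intramodular-permuted modules keep density but lose
           connectivity", {
    ratios <- c(); kims <- c()
    for (r in 1:10) {
        sim <- simulateScenario("intramodular_permuted", nModules = 4,
                                moduleSizes = c(40, 40, 40, 40),
                                nSamples = 60, seed = 200 + r)
        lab <- moduleLabels(sim)
        dOnly <- moduleTruth(sim)$module[
            moduleTruth(sim)$preservation == "density_only"][1]
        g <- generalDensityStats(
            toAdjacency(computeCorrelation(testExpression(sim))),
            lab)
        gr <- generalDensityStats(
            toAdjacency(computeCorrelation(refExpression(sim))),
            lab)
        k <- generalConnectivityStats(
            toAdjacency(computeCorrelation(refExpression(sim))),
            toAdjacency(computeCorrelation(testExpression(sim))),
            lab)
        ratios <- c(ratios, gr$meanAdj[gr$module == dOnly] /
                            g$meanAdj[g$module == dOnly])
        kims <- c(kims, k$cor.kIM[k$module == dOnly])
    }
    expect_true(all(ratios > 0.8 & ratios < 1.25))
    expect_lt(mean(abs(kims)), 0.3)
})

test_that("pathway modules preserve connectivity patterns at low density", {
    corcors <- c(); densRatio <- c()
    for (r in 1:10) {
        sim <- simulateScenario("pathway_small", nModules = 3,
                                moduleSizes = c(25, 40, 60),
                                nSamples = 60, seed = 300 + r)
        lab <- moduleLabels(sim)
        Xr <- refExpression(sim); Xt <- testExpression(sim)
        pres <- moduleTruth(sim)$module[moduleTruth(sim)$preserved][1]
        cc <- corConnectivityStats(Xr, Xt, lab)
        corcors <- c(corcors, cc$cor.cor[cc$module == pres])
        # density of the pathway module vs a single source cluster: the
        # module mixes clusters, so its test density must be much lower
        A <- toAdjacency(computeCorrelation(Xt))
        idx <- which(lab == pres)
        modDens <- mean(vectorizeUpper(A[idx, idx]))
        # preserved clusters occupy consecutive node-index blocks, so the
        # latent cluster of each module member is known exactly
        sc <- scenarioInfo(sim)
        clSize <- ceiling(1.25 * sum(sc$moduleSizes) / sc$nClusters)
        cl <- (idx - 1) %/% clSize
        sub <- A[idx, idx]
        same <- outer(cl, cl, "==") & upper.tri(sub)
        densRatio <- c(densRatio, modDens / mean(sub[same]))
    }
    expect_true(all(corcors >= 0.5))
    expect_lt(mean(densRatio), 0.5)
})

test_that("the 4-point grading rule reproduces its defining examples", {
    expect_equal(gradeStatistic(c(12, 15, 0.5, 1.9),
                                c(TRUE, TRUE, FALSE, FALSE)), 4L)
    expect_equal(gradeStatistic(c(8, 9, 1, 3),
                                c(TRUE, TRUE, FALSE, FALSE)), 3L)
    # 5 modules, exactly 1 misclassified at the optimal cut
    expect_equal(gradeStatistic(c(12, 11, 1.5, 1, 13),
                                c(TRUE, TRUE, FALSE, FALSE, FALSE)), 2L)
    # hopeless interleaving
    expect_equal(gradeStatistic(c(1, 5, 2, 6, 3, 7),
                                rep(c(TRUE, FALSE), 3)), 1L)
    # rank rule: preserved modules must have the smaller values
    expect_equal(gradeStatistic(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                                rule = "rank_separation"), 4L)
    # 5 modules, one false preserved at the best cut: exactly the 20%
    # allowance
    expect_equal(gradeStatistic(c(1, 3, 2, 4, 5),
                                c(TRUE, TRUE, FALSE, FALSE, FALSE),
                                rule = "rank_separation"), 2L)
    expect_error(gradeStatistic(c(1, 2), c(TRUE, TRUE)), "non-preserved")
})
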