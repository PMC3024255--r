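# Permutation machinery, Z statistics, composites, median ranks,
# summary p-values, and the end-to-end driver contracts.

test_that("label permutation preserves the label multiset and is
           seed-reproducible", {
    lab <- makeLabels(c(10, 20, 5), paste0("g", 1:50))
    p1 <- permuteModuleLabels(lab, seed = 4)
    expect_identical(sort(as.vector(p1)), sort(as.vector(lab)))
    expect_identical(names(p1), names(lab))
    p2 <- permuteModuleLabels(lab, seed = 4)
    expect_identical(p1, p2)
    p3 <- permuteModuleLabels(lab, seed = 5)
    expect_false(identical(p1, p3))
})

test_that("zStatistic standardizes correctly and handles degenerate
           nulls", {
    null <- c(1, 3, 2)                       # mean 2, sd 1
    z <- zStatistic(5, null)
    expect_equal(z$Z, 3)
    expect_equal(z$nullMean, 2)
    expect_equal(z$nullSD, 1)
    # observed 5, mean 2, sd 1.5 -> Z = 2
    expect_equal(zStatistic(5, c(0.5, 3.5, 2))$Z, 2)
    # observed at the null mean: Z = 0, p = 0.5
    z0 <- zStatistic(2, null)
    expect_equal(z0$Z, 0)
    expect_equal(z0$log10.p, log10(0.5), tolerance = 1e-12)
    # constant null: undefined Z
    expect_true(is.na(zStatistic(5, c(2, 2, 2))$Z))
    # fewer than 2 valid null samples: undefined
    expect_true(is.na(zStatistic(5, c(1, NA, NA))$Z))
    # missing samples are dropped and counted
    expect_equal(zStatistic(5, c(1, 3, 2, NA))$nValid, 3)
})

test_that("composite Z follows the median/mean aggregation rules", {
    z <- c(meanSignAwareCorDat = 8, propVarExplained = 8,
           meanSignAwareKME = 8, cor.adj = 4, cor.kIM = 4,
           cor.cor = 4, cor.kME = 4)
    cz <- compositeZ(z, "correlation")
    expect_equal(cz$Zdensity, 8)
    expect_equal(cz$Zconnectivity, 4)
    expect_equal(cz$Zsummary, 6)
    # all components equal c: every composite equals c
    zc <- compositeZ(replace(z, seq_along(z), 3), "correlation")
    expect_equal(unlist(zc), c(Zdensity = 3, Zconnectivity = 3,
                               Zsummary = 3))
    # median, not mean, within the sets
    z2 <- c(meanSignAwareCorDat = 1, propVarExplained = 2,
            meanSignAwareKME = 10, cor.adj = 1, cor.kIM = 2,
            cor.cor = 10, cor.kME = 100)
    cz2 <- compositeZ(z2, "correlation")
    expect_equal(cz2$Zdensity, 2)
    expect_equal(cz2$Zconnectivity, 6)
    # general networks: density composite is the meanAdj Z alone
    zg <- c(meanAdj = 5, cor.adj = 1, cor.kIM = 3)
    czg <- compositeZ(zg, "general")
    expect_equal(czg$Zdensity, 5)
    expect_equal(czg$Zconnectivity, 2)
    expect_equal(czg$Zsummary, 3.5)
    # missing components are dropped with a warning
    zm <- replace(z, "cor.kME", NA)
    expect_warning(czm <- compositeZ(zm, "correlation"), "dropping")
    expect_equal(czm$Zconnectivity, 4)
})

test_that("median ranks: best module ranks 1, ties average, oracle
           agreement on random values", {
    stats <- c("meanSignAwareCorDat", "propVarExplained",
               "meanSignAwareKME", "cor.adj", "cor.kIM", "cor.cor",
               "cor.kME")
    # one module dominates every statistic
    obs <- rbind(best = rep(1, 7), mid = rep(.5, 7), low = rep(.1, 7))
    colnames(obs) <- stats
    mr <- medianRank(obs, "correlation")
    expect_equal(mr$medianRank[mr$module == "best"], 1)
    expect_equal(mr$medianRank[mr$module == "low"], 3)
    # two identical modules share average ranks
    obs2 <- rbind(a = rep(.8, 7), b = rep(.8, 7))
    colnames(obs2) <- stats
    mr2 <- medianRank(obs2, "correlation")
    expect_equal(mr2$medianRank, c(1.5, 1.5))
    # random values vs a brute-force sort-and-median oracle
    set.seed(12)
    obs3 <- matrix(rnorm(21), 3, 7, dimnames = list(c("x", "y", "z"),
                                                    stats))
    mr3 <- medianRank(obs3, "correlation")
    dSet <- stats[1:3]; cSet <- stats[4:7]
    for (mod in rownames(obs3)) {
        rk <- sapply(stats, function(s)
            rank(-obs3[, s])[mod])
        names(rk) <- stats
        expect_equal(mr3$medianRank.density[mr3$module == mod],
                     median(rk[dSet]))
        expect_equal(mr3$medianRank.connectivity[mr3$module == mod],
                     median(rk[cSet]))
        expect_equal(mr3$medianRank[mr3$module == mod],
                     (median(rk[dSet]) + median(rk[cSet])) / 2)
    }
    # undefined observed values rank last
    obs4 <- obs3
    obs4["x", ] <- NA
    mr4 <- medianRank(obs4, "correlation")
    expect_equal(mr4$medianRank[mr4$module == "x"], 3)
})

test_that("summary log10 p is the median over the composite statistics", {
    stats <- c("meanSignAwareCorDat", "propVarExplained",
               "meanSignAwareKME", "cor.adj", "cor.kIM", "cor.cor",
               "cor.kME")
    lp <- setNames(rep(log10(0.5), 7), stats)
    expect_equal(summaryLogP(lp, "correlation"), log10(0.5),
                 tolerance = 1e-12)
    # median, not minimum: one extreme component does not dominate
    lp2 <- setNames(c(-20, rep(log10(0.5), 6)), stats)
    expect_equal(summaryLogP(lp2, "correlation"), log10(0.5),
                 tolerance = 1e-12)
    # oracle: median of log10 upper-tail normal p over a random Z vector
    set.seed(31)
    z <- setNames(rnorm(7, 2, 3), stats)
    lp3 <- pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)
    expect_equal(summaryLogP(lp3, "correlation"), median(lp3),
                 tolerance = 1e-12)
})

test_that("permutation nulls match direct same-size node-set sampling for
           module density", {
    # the engine's null for meanAdj must be distributed like densities of
    # random node sets of the module's size
    A <- makeAdj(40, seed = 2)
    lab <- makeLabels(c(10, 10, 10, 10), rownames(A), greyRest = FALSE)
    mp <- modulePreservation(A, A, lab, dataType = "adjacency",
                             nPermutations = 150, seed = 7,
                             goldSize = 10, returnNulls = TRUE,
                             calculateQuality = FALSE,
                             calculateClusterCoef = FALSE)
    nulls <- nullSamples(mp)$samples[, "M01", "meanAdj"]
    direct <- withr::with_seed(99, replicate(150, {
        idx <- sample(40, 10)
        mean(vectorizeUpper(A[idx, idx]))
    }))
    expect_gt(t.test(nulls, direct)$p.value, 0.01)
    expect_gt(var.test(nulls, direct)$p.value, 0.01)
})

test_that("the driver honors nPermutations = 0, undefined-sd modules, and
           bit-identical reproducibility", {
    st <- withr::with_seed(14, {
        ids <- paste0("g", 1:30)
        Xr <- matrix(rnorm(20 * 30), 20, dimnames = list(NULL, ids))
        Xt <- matrix(rnorm(20 * 30), 20, dimnames = list(NULL, ids))
        list(Xr = Xr, Xt = Xt, lab = makeLabels(c(10, 10, 10), ids))
    })
    mp0 <- modulePreservation(st$Xr, st$Xt, st$lab, nPermutations = 0,
                              seed = 1, goldSize = 10,
                              calculateClusterCoef = FALSE)
    expect_false("Z" %in% names(preservationStats(mp0)))
    expect_false("Zsummary" %in% names(compositeStats(mp0)))
    expect_true("medianRank" %in% names(compositeStats(mp0)))

    # a module equal to the whole network is constant under permutation
    idsAll <- paste0("g", 1:12)
    Xa <- withr::with_seed(3, matrix(rnorm(15 * 12), 15,
                                     dimnames = list(NULL, idsAll)))
    labAll <- setNames(rep("M01", 12), idsAll)
    mpA <- suppressWarnings(
        modulePreservation(Xa, Xa, labAll, nPermutations = 10, seed = 1,
                           goldSize = 12, calculateQuality = FALSE,
                           calculateClusterCoef = FALSE))
    rs <- preservationStats(mpA)
    expect_true(is.na(rs$Z[rs$module == "M01" &
                           rs$statistic == "meanAdj"]))

    # same seed, config, inputs: identical output tables
    run <- function() modulePreservation(st$Xr, st$Xt, st$lab,
                                         nPermutations = 15, seed = 42,
                                         goldSize = 15,
                                         calculateClusterCoef = FALSE)
    expect_identical(preservationStats(run()), preservationStats(run()))
    expect_identical(compositeStats(run()), compositeStats(run()))
})

test_that("Zsummary equals the mean of its composites and evidence flags
           follow the thresholds", {
    st <- makeCorStudy(m = 30, sizes = c(10, 10), seed = 5)
    mp <- modulePreservation(st$Xref, st$Xtest, st$labels,
                             nPermutations = 25, seed = 2, goldSize = 10,
                             calculateClusterCoef = FALSE)
    cm <- compositeStats(mp)
    ok <- complete.cases(cm$Zdensity, cm$Zconnectivity)
    expect_equal(cm$Zsummary[ok],
                 (cm$Zdensity[ok] + cm$Zconnectivity[ok]) / 2)
    expect_true(all(cm$evidence[!is.na(cm$Zsummary) & cm$Zsummary > 10]
                    == "strong"))
    expect_true(all(cm$evidence[!is.na(cm$Zsummary) & cm$Zsummary < 2]
                    == "none"))
    # long results carry Bonferroni-adjusted log10 p alongside raw
    rs <- preservationStats(mp)
    expect_true(all(rs$log10.p.bonferroni >= rs$log10.p, na.rm = TRUE))
    expect_true(all(rs$log10.p.bonferroni <= 0, na.rm = TRUE))
})
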