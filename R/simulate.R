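# Synthetic paired-network generator: eigengene-seeded co-expression
# modules under seven benchmark scenarios, plus the 4-point grading
# harness for evaluating how well a statistic separates preserved from
# non-preserved modules.

#' Scenario specification for the synthetic-data generator
#'
#' Builds the parameter list for one of the seven simulation scenarios.
#' Each module is seeded by a latent profile; node i's profile is
#' `r_i * seed + sqrt(1 - r_i^2) * noise` with membership correlations
#' `r_i` evenly spaced in `[minCor, maxCor]` across the module. The
#' scenarios differ in how the test data relate to the reference data:
#'
#' * `weak`: 20 modules of 200 nodes, correlations 0.3-0.6; half the
#'   modules preserved (same seed and r in the test set, fresh noise),
#'   half regenerated as independent noise.
#' * `strong`: 10 modules, sizes evenly spaced 100-400, correlations
#'   0.6-0.95; modules 1-5 preserved, 6-10 independent noise.
#' * `permuted`: modules simulated in both sets but the node-to-module
#'   assignment is randomly permuted between the networks; nothing is
#'   preserved.
#' * `half_permuted`: modules 1-5 preserved; modules 6-10 simulated in
#'   the test set with membership permuted among their nodes.
#' * `intramodular_permuted`: modules 1-5 are regenerated preserved and
#'   then node identities are shuffled within each module in the test set
#'   (density kept, connectivity destroyed); 6-10 independent noise.
#' * `pathway_small` / `pathway_large`: modules assembled by interleaving
#'   nodes from 5 underlying preserved (resp. non-preserved) clusters, so
#'   connectivity is preserved but density is low; module sizes evenly
#'   spaced 25-100 (small) or 100-500 (large), endpoints attained.
#'
#' Grey (unassigned) nodes are independent noise in both sets; their
#' count defaults to 25% of the proper-module nodes.
#'
#' @param scenario Scenario id.
#' @param nSamples Samples per data set.
#' @param nModules Number of proper modules (`weak`: total; pathway
#'   scenarios: per preservation group).
#' @param moduleSizes Optional explicit module sizes (overrides the
#'   scenario defaults).
#' @param minCor,maxCor Membership-correlation range.
#' @param greyFraction Grey nodes as a fraction of proper-module nodes.
#' @param nClusters Source clusters per group in the pathway scenarios.
#' @return Named list of generator parameters.
#' @export
scenarioSpec <- function(scenario = c("weak", "strong", "permuted",
                                      "half_permuted",
                                      "intramodular_permuted",
                                      "pathway_small", "pathway_large"),
                         nSamples = 100L, nModules = NULL,
                         moduleSizes = NULL, minCor = NULL, maxCor = NULL,
                         greyFraction = 0.25, nClusters = 5L) {
    scenario <- match.arg(scenario)
    defCor <- switch(scenario, weak = c(0.3, 0.6), c(0.6, 0.95))
    if (is.null(minCor)) minCor <- defCor[1L]
    if (is.null(maxCor)) maxCor <- defCor[2L]
    stopifnot(minCor > 0, minCor <= maxCor, maxCor < 1)
    if (is.null(nModules))
        nModules <- switch(scenario, weak = 20L,
                           pathway_small = 5L, pathway_large = 5L, 10L)
    if (is.null(moduleSizes)) {
        moduleSizes <- switch(scenario,
            weak = rep(200L, nModules),
            pathway_small = round(seq(25, 100, length.out = nModules)),
            pathway_large = round(seq(100, 500, length.out = nModules)),
            round(seq(100, 400, length.out = nModules)))
    } else {
        nModules <- if (scenario %in% c("pathway_small", "pathway_large"))
            length(moduleSizes) else length(moduleSizes)
    }
    if (any(moduleSizes < 3L))
        stop("module sizes must be at least 3")
    list(scenario = scenario, nSamples = as.integer(nSamples),
         nModules = as.integer(nModules),
         moduleSizes = as.integer(moduleSizes),
         minCor = minCor, maxCor = maxCor,
         greyFraction = greyFraction, nClusters = as.integer(nClusters))
}

# Simulate one structured module: node i = r_i * seedProfile +
# sqrt(1 - r_i^2) * fresh noise. `r` is recycled per node.
.simModule <- function(seedProfile, r) {
    m <- length(seedProfile)
    noise <- matrix(stats::rnorm(m * length(r)), m)
    sweep(noise, 2L, sqrt(1 - r^2), `*`) +
        outer(seedProfile, r)
}

#' Simulate a paired reference/test co-expression study
#'
#' Generates a [SimulatedStudy-class] under one of the seven scenarios
#' described in [scenarioSpec()], with known per-module preservation
#' ground truth (`both`, `density_only`, `connectivity_only`, `none`).
#' The same scenario and seed reproduce the study bit for bit.
#'
#' @param scenario A scenario id (passed to [scenarioSpec()]) or a
#'   specification list returned by it.
#' @param seed Integer seed.
#' @param ... Further arguments to [scenarioSpec()] when `scenario` is an
#'   id.
#' @return A [SimulatedStudy-class] object.
#' @examples
#' sim <- simulateScenario("strong", nModules = 4,
#'                         moduleSizes = c(30, 40, 50, 60),
#'                         nSamples = 30, seed = 1)
#' moduleTruth(sim)
#' @export
simulateScenario <- function(scenario = "strong", seed = 1L, ...) {
    spec <- if (is.list(scenario)) scenario else scenarioSpec(scenario, ...)
    spec$seed <- as.integer(seed)
    .withSeed(seed, .simulateFromSpec(spec))
}

.simulateFromSpec <- function(spec) {
    if (spec$scenario %in% c("pathway_small", "pathway_large"))
        return(.simulatePathway(spec))
    m <- spec$nSamples
    sizes <- spec$moduleSizes
    nMod <- spec$nModules
    mods <- sprintf("M%02d", seq_len(nMod))
    nProper <- sum(sizes)
    nGrey <- round(spec$greyFraction * nProper)
    n <- nProper + nGrey
    nodeIds <- sprintf("N%05d", seq_len(n))
    labels <- c(rep(mods, times = sizes), rep("grey", nGrey))
    names(labels) <- nodeIds

    preservedIdx <- switch(spec$scenario,
        weak = seq_len(floor(nMod / 2)),
        strong = seq_len(floor(nMod / 2)),
        permuted = integer(0),
        half_permuted = seq_len(floor(nMod / 2)),
        intramodular_permuted = seq_len(floor(nMod / 2)))
    type <- rep("none", nMod)
    type[preservedIdx] <- switch(spec$scenario,
        intramodular_permuted = "density_only", "both")

    Xref <- matrix(NA_real_, m, n, dimnames = list(
        sprintf("ref_s%03d", seq_len(m)), nodeIds))
    Xtest <- matrix(NA_real_, m, n, dimnames = list(
        sprintf("test_s%03d", seq_len(m)), nodeIds))

    rByModule <- lapply(sizes, function(s)
        seq(spec$minCor, spec$maxCor, length.out = s))
    seeds <- matrix(stats::rnorm(m * nMod), m)

    # reference: every module structured
    for (q in seq_len(nMod)) {
        idx <- which(labels == mods[q])
        Xref[, idx] <- .simModule(seeds[, q], rByModule[[q]])
    }

    # test side by scenario
    if (spec$scenario %in% c("weak", "strong", "intramodular_permuted")) {
        for (q in seq_len(nMod)) {
            idx <- which(labels == mods[q])
            if (type[q] == "none") {
                Xtest[, idx] <- matrix(stats::rnorm(m * length(idx)), m)
            } else {
                prof <- .simModule(seeds[, q], rByModule[[q]])
                if (spec$scenario == "intramodular_permuted")
                    prof <- prof[, sample(ncol(prof)), drop = FALSE]
                Xtest[, idx] <- prof
            }
        }
    } else {
        # permuted / half_permuted: fresh test seeds, membership permuted
        testSeeds <- matrix(stats::rnorm(m * nMod), m)
        permSet <- if (spec$scenario == "permuted") seq_len(nMod)
                   else setdiff(seq_len(nMod), preservedIdx)
        for (q in preservedIdx) {
            idx <- which(labels == mods[q])
            Xtest[, idx] <- .simModule(seeds[, q], rByModule[[q]])
        }
        permNodes <- which(labels %in% mods[permSet])
        testLab <- labels
        testLab[permNodes] <- labels[sample(permNodes)]
        for (q in permSet) {
            idx <- which(testLab == mods[q])
            # membership strengths are shuffled over the permuted members,
            # so a node's test-side r is unrelated to its reference module
            Xtest[, idx] <- .simModule(testSeeds[, q],
                sample(seq(spec$minCor, spec$maxCor,
                           length.out = length(idx))))
        }
    }

    greyIdx <- which(labels == "grey")
    if (length(greyIdx)) {
        Xref[, greyIdx] <- matrix(stats::rnorm(m * length(greyIdx)), m)
        Xtest[, greyIdx] <- matrix(stats::rnorm(m * length(greyIdx)), m)
    }

    truth <- data.frame(module = mods, size = sizes,
                        preservation = type,
                        preserved = type != "none",
                        row.names = NULL)
    methods::new("SimulatedStudy", refExpr = Xref, testExpr = Xtest,
                 labels = labels, truth = truth, scenario = spec)
}

# Pathway scenarios: the correlation structure lives in underlying
# clusters (preserved clusters reuse their seeds in the test set;
# non-preserved clusters keep structure but with membership permuted, as
# in the half-permuted scenario). The user-visible modules draw equal
# node counts from every cluster of their group, so their connectivity
# pattern follows the cluster blocks (preserved for the preserved group)
# while their density is low. Unsampled cluster nodes stay in the
# network as unassigned (grey) nodes, keeping the permutation null as
# structure-rich as the modules themselves.
.simulatePathway <- function(spec) {
    m <- spec$nSamples
    sizes <- spec$moduleSizes       # per group
    nMod <- spec$nModules           # per group
    nC <- spec$nClusters
    groupNeed <- sum(sizes)
    clSize <- ceiling(1.25 * groupNeed / nC)
    groupTotal <- nC * clSize
    nGreyNoise <- round(spec$greyFraction * 2L * groupNeed)
    n <- 2L * groupTotal + nGreyNoise
    nodeIds <- sprintf("N%05d", seq_len(n))

    Xref <- matrix(NA_real_, m, n, dimnames = list(
        sprintf("ref_s%03d", seq_len(m)), nodeIds))
    Xtest <- matrix(NA_real_, m, n, dimnames = list(
        sprintf("test_s%03d", seq_len(m)), nodeIds))
    labels <- stats::setNames(rep("grey", n), nodeIds)

    # cluster structure per group; returns the per-cluster node pools
    simGroup <- function(offset, preservedGroup) {
        clusterIdx <- split(offset + seq_len(groupTotal),
                            rep(seq_len(nC), each = clSize))
        seeds <- matrix(stats::rnorm(m * nC), m)
        for (cl in seq_len(nC)) {
            idx <- clusterIdx[[cl]]
            r <- seq(spec$minCor, spec$maxCor, length.out = clSize)
            Xref[, idx] <<- .simModule(seeds[, cl], r)
            if (preservedGroup)
                Xtest[, idx] <<- .simModule(seeds[, cl], r)
        }
        if (!preservedGroup) {
            # test structure exists but membership is permuted across the
            # group, so nothing about these clusters is preserved
            testSeeds <- matrix(stats::rnorm(m * nC), m)
            permuted <- sample(offset + seq_len(groupTotal))
            permIdx <- split(permuted, rep(seq_len(nC), each = clSize))
            for (cl in seq_len(nC)) {
                idx <- permIdx[[cl]]
                Xtest[, idx] <<- .simModule(testSeeds[, cl],
                    sample(seq(spec$minCor, spec$maxCor,
                               length.out = clSize)))
            }
        }
        clusterIdx
    }
    poolsP <- simGroup(0L, TRUE)
    poolsN <- simGroup(groupTotal, FALSE)

    # assemble the user-visible modules: equal draws from every cluster
    drawModules <- function(pools, prefix) {
        pools <- lapply(pools, sample)      # random draw order
        for (q in seq_len(nMod)) {
            take <- diff(round(seq(0, sizes[q], length.out = nC + 1L)))
            members <- integer(0)
            for (cl in seq_len(nC)) {
                members <- c(members, pools[[cl]][seq_len(take[cl])])
                pools[[cl]] <- pools[[cl]][-seq_len(take[cl])]
            }
            labels[nodeIds[members]] <<- sprintf("%s%02d", prefix, q)
        }
    }
    drawModules(poolsP, "P")
    drawModules(poolsN, "Q")

    greyNoiseIdx <- 2L * groupTotal + seq_len(nGreyNoise)
    if (nGreyNoise > 0L) {
        Xref[, greyNoiseIdx] <- matrix(stats::rnorm(m * nGreyNoise), m)
        Xtest[, greyNoiseIdx] <- matrix(stats::rnorm(m * nGreyNoise), m)
    }

    mods <- c(sprintf("P%02d", seq_len(nMod)), sprintf("Q%02d", seq_len(nMod)))
    truth <- data.frame(
        module = mods,
        size = rep(sizes, 2L),
        preservation = rep(c("connectivity_only", "none"), each = nMod),
        preserved = rep(c(TRUE, FALSE), each = nMod),
        row.names = NULL)
    methods::new("SimulatedStudy", refExpr = Xref, testExpr = Xtest,
                 labels = labels, truth = truth, scenario = spec)
}

#' Grade how well a statistic separates preserved from non-preserved
#' modules
#'
#' Applies the 4-point grading rule used to benchmark preservation
#' statistics. Under the `z_thresholds` rule (for Z-scale statistics,
#' where preserved modules should score *high*): grade 4 if every
#' preserved module has Z >= 10 and every non-preserved module Z <= 2;
#' grade 3 if preserved and non-preserved are perfectly separated but a
#' threshold is violated; grade 2 if the best separating cut misclassifies
#' at most 20% of the modules; grade 1 otherwise. Under the
#' `rank_separation` rule (for medianRank-type statistics, where preserved
#' modules should score *low* and no absolute thresholds exist): grade 4
#' for perfect separation, otherwise the same 20%-misclassification
#' ladder. The misclassification cut maximizes accuracy, ties broken
#' toward fewer false preserved calls.
#'
#' @param values Named per-module statistic values.
#' @param preserved Logical vector (same order/names): ground truth.
#' @param rule `"z_thresholds"` or `"rank_separation"`.
#' @return Integer grade in 1..4.
#' @examples
#' gradeStatistic(c(12, 15, 0.5, 1.9), c(TRUE, TRUE, FALSE, FALSE))  # 4
#' @export
gradeStatistic <- function(values, preserved,
                           rule = c("z_thresholds", "rank_separation")) {
    rule <- match.arg(rule)
    if (!any(preserved) || all(preserved))
        stop("grading needs at least one preserved and one ",
             "non-preserved module")
    if (any(!is.finite(values)))
        stop("all statistic values must be finite for grading")
    # orient so that preserved modules should score high
    v <- if (rule == "rank_separation") -values else values
    pres <- v[preserved]
    nonp <- v[!preserved]
    separated <- min(pres) > max(nonp)
    if (rule == "z_thresholds") {
        if (all(values[preserved] >= 10) && all(values[!preserved] <= 2))
            return(4L)
        if (separated)
            return(3L)
    } else if (separated) {
        return(4L)
    }
    if (.bestCutMisclassification(v, preserved) <= 0.2)
        return(2L)
    1L
}

# Fraction of modules misclassified by the accuracy-maximizing threshold
# (predict preserved when value > cut); ties toward fewer false preserved.
.bestCutMisclassification <- function(v, preserved) {
    cuts <- c(sort(unique(v)), Inf)
    best <- Inf
    bestFP <- Inf
    for (cut in cuts) {
        call <- v >= cut
        mis <- sum(call != preserved)
        fp <- sum(call & !preserved)
        if (mis < best || (mis == best && fp < bestFP)) {
            best <- mis
            bestFP <- fp
        }
    }
    best / length(v)
}
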