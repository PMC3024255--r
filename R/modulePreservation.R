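# End-to-end module preservation analysis: observed statistics,
# permutation nulls, Z statistics, composites.

#' Module preservation analysis between a reference and a test network
#'
#' Evaluates whether modules defined in a reference network are preserved
#' in an independent test network. Both inputs are either expression
#' matrices (samples x nodes; a soft-threshold correlation network is
#' built internally) or precomputed adjacency matrices. Observed density-,
#' connectivity- and separability-based preservation statistics are
#' computed per module, together with reference-side module quality
#' statistics, and standardized against a permutation null in which module
#' labels are randomly reassigned to nodes: each permutation redefines a
#' module's node set and recomputes all reference- and test-side
#' quantities on it, so every statistic is compared against random modules
#' of the same size. Permutation Z statistics are summarized into
#' `Zdensity`, `Zconnectivity` and `Zsummary` (their mean), the rank-based
#' `medianRank` composites, and a summary log10 p-value.
#'
#' Two improper modules are always evaluated alongside the user's modules:
#' `grey` (all unassigned nodes) and `gold` (a random sample of
#' `goldSize` nodes representing the whole network). Both are flagged
#' improper and excluded from the median-rank ranking and from
#' separability pairs.
#'
#' Interpretation thresholds for `Zsummary`: above 10, strong evidence of
#' preservation; between 2 and 10, weak to moderate evidence; below 2, no
#' evidence.
#'
#' @param reference,test Expression matrices (samples x nodes) or
#'   adjacency matrices over a shared node universe.
#' @param labels Named module assignment for the reference network
#'   (`"0"`/`"grey"` = unassigned; `"gold"` is reserved).
#' @param dataType `"expression"` or `"adjacency"`.
#' @param networkType `"unsigned"` (adjacency `|cor|^beta`) or `"signed"`
#'   (`((1+cor)/2)^beta`).
#' @param corMethod Correlation estimator for expression input.
#' @param power Soft-thresholding power; defaults to 6 (unsigned) or
#'   12 (signed).
#' @param nPermutations Number of label permutations for the null
#'   (0 skips Z statistics entirely and reports observed values only).
#' @param seed Integer seed; the whole run is reproducible bit-for-bit.
#' @param goldSize Size of the random whole-network module
#'   (capped at the number of nodes).
#' @param minModuleSize Smaller modules are excluded with a warning.
#' @param calculateQuality Also compute reference-side quality statistics
#'   (their null permutes the reference labels the same way).
#' @param calculateClusterCoef Include the clustering-coefficient and MAR
#'   statistics (the most expensive ones; not part of any composite).
#' @param permutePool `"all"` permutes labels over all nodes including
#'   grey; `"assigned"` only over proper-module nodes.
#' @param returnNulls Keep the raw permutation null samples in the result.
#' @param verbose Print progress.
#' @return A [ModulePreservation-class] object.
#'
#' @examples
#' sim <- simulateScenario("strong", nModules = 4, moduleSizes = c(30, 40, 50, 60),
#'                         nSamples = 40, seed = 7)
#' mp <- modulePreservation(refExpression(sim), testExpression(sim),
#'                          moduleLabels(sim), nPermutations = 20, seed = 1,
#'                          calculateClusterCoef = FALSE)
#' compositeStats(mp)
#' @export
modulePreservation <- function(reference, test, labels,
                               dataType = c("expression", "adjacency"),
                               networkType = c("unsigned", "signed"),
                               corMethod = c("pearson", "spearman", "bicor"),
                               power = NULL,
                               nPermutations = 100L,
                               seed = 1L,
                               goldSize = 1000L,
                               minModuleSize = 3L,
                               calculateQuality = TRUE,
                               calculateClusterCoef = TRUE,
                               permutePool = c("all", "assigned"),
                               returnNulls = FALSE,
                               verbose = FALSE) {
    dataType <- match.arg(dataType)
    networkType <- match.arg(networkType)
    corMethod <- match.arg(corMethod)
    permutePool <- match.arg(permutePool)
    stopifnot(nPermutations >= 0L)
    ctx <- .buildContext(reference, test, dataType, networkType, corMethod,
                        power, calculateClusterCoef, calculateQuality)
    ms <- .moduleIndexSets(ctx, labels, minModuleSize, includeGrey = TRUE)
    labVec <- ms$labels
    networkClass <- if (dataType == "expression") "correlation" else "general"

    run <- .withSeed(seed, {
        gs <- min(goldSize, ctx$n)
        idxList <- ms$idxList
        if (gs >= minModuleSize)
            idxList$gold <- sort(sample.int(ctx$n, gs))
        mods <- names(idxList)
        proper <- !(mods %in% c("grey", "gold"))
        if (verbose)
            message("evaluating observed statistics for ", length(mods),
                    " modules")
        observed <- .evalModules(ctx, idxList, proper)
        nulls <- NULL
        if (nPermutations > 0L) {
            nulls <- array(NA_real_,
                           c(nPermutations, length(mods),
                             length(ctx$statNames)),
                           dimnames = list(NULL, mods, ctx$statNames))
            pool <- if (permutePool == "all") seq_len(ctx$n)
                    else which(labVec != "grey")
            for (b in seq_len(nPermutations)) {
                permLab <- labVec
                permLab[pool] <- labVec[pool][sample(length(pool))]
                pIdx <- lapply(mods, function(q) {
                    if (q == "gold") sort(sample.int(ctx$n, gs))
                    else which(permLab == q)
                })
                names(pIdx) <- mods
                nulls[b, , ] <- .evalModules(ctx, pIdx, proper)
                if (verbose && b %% 20L == 0L)
                    message("  permutation ", b, "/", nPermutations)
            }
        }
        list(idxList = idxList, observed = observed, nulls = nulls,
             proper = proper, goldSize = gs)
    })

    .assembleResults(ctx, run, networkClass, ms$excluded,
                     nPermutations, seed, returnNulls,
                     list(dataType = dataType, networkType = networkType,
                          corMethod = corMethod, power = ctx$power,
                          goldSize = run$goldSize,
                          minModuleSize = minModuleSize,
                          permutePool = permutePool))
}

# Turn observed + null arrays into the result object.
.assembleResults <- function(ctx, run, networkClass, excluded,
                             nPermutations, seed, returnNulls, cfg) {
    observed <- run$observed
    mods <- rownames(observed)
    sizes <- lengths(run$idxList)
    statNames <- colnames(observed)
    long <- data.frame(
        module = rep(mods, times = length(statNames)),
        moduleSize = rep(sizes, times = length(statNames)),
        statistic = rep(statNames, each = length(mods)),
        observed = as.vector(observed),
        row.names = NULL)

    zMat <- NULL
    if (!is.null(run$nulls)) {
        zres <- vapply(statNames, function(s) {
            vapply(mods, function(q) {
                zs <- zStatistic(observed[q, s], run$nulls[, q, s])
                c(zs$nullMean, zs$nullSD, zs$Z, zs$log10.p,
                  as.numeric(zs$nValid))
            }, numeric(5L))
        }, matrix(0, 5L, length(mods)))
        # zres: 5 x modules x stats
        long$nullMean <- as.vector(zres[1L, , ])
        long$nullSD <- as.vector(zres[2L, , ])
        long$Z <- as.vector(zres[3L, , ])
        long$log10.p <- as.vector(zres[4L, , ])
        long$log10.p.bonferroni <- pmin(0, long$log10.p +
                                        log10(length(mods)))
        long$nNullValid <- as.integer(zres[5L, , ])
        zMat <- matrix(long$Z, nrow = length(mods),
                       dimnames = list(mods, statNames))
    }

    proper <- run$proper
    comp <- data.frame(module = mods, moduleSize = as.integer(sizes),
                       improper = !proper, row.names = NULL)
    if (!is.null(zMat)) {
        cz <- t(vapply(mods, function(q) {
            z <- compositeZ(zMat[q, ], networkClass)
            unlist(z)
        }, numeric(3L)))
        comp$Zdensity <- cz[, "Zdensity"]
        comp$Zconnectivity <- cz[, "Zconnectivity"]
        comp$Zsummary <- cz[, "Zsummary"]
    }
    # median ranks over proper modules only
    comp$medianRank.density <- NA_real_
    comp$medianRank.connectivity <- NA_real_
    comp$medianRank <- NA_real_
    if (sum(proper) >= 2L) {
        mr <- medianRank(observed[proper, , drop = FALSE], networkClass)
        ii <- match(mr$module, comp$module)
        comp$medianRank.density[ii] <- mr$medianRank.density
        comp$medianRank.connectivity[ii] <- mr$medianRank.connectivity
        comp$medianRank[ii] <- mr$medianRank
    }
    if (!is.null(zMat)) {
        lpMat <- matrix(long$log10.p, nrow = length(mods),
                        dimnames = list(mods, statNames))
        comp$summary.log10.p <- vapply(mods, function(q)
            summaryLogP(lpMat[q, ], networkClass), numeric(1L))
        comp$evidence <- .evidenceFlag(comp$Zsummary)
    }

    metadata <- c(cfg, list(
        nNodes = ctx$n,
        nPermutations = nPermutations,
        seed = seed,
        networkClass = networkClass,
        excludedModules = excluded,
        improperModules = mods[!proper],
        statistics = statNames,
        compositeSets = .compositeSets(networkClass),
        separabilityConvention = if (ctx$networkType == "unsigned")
            "1 - |cor|" else "1 - cor",
        perModuleSeparability = "min over other proper modules",
        nUndefinedObserved = sum(is.na(observed))))

    nulls <- if (returnNulls && !is.null(run$nulls))
        list(samples = run$nulls) else list()
    methods::new("ModulePreservation", results = long, composites = comp,
                 nulls = nulls, metadata = metadata)
}
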