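# Correlation-network-specific preservation statistics, eigennode
# separability, and reference-side module quality statistics.

# Shared expression-mode context for the wrapper functions below.
.corCtx <- function(Xref, Xtest, networkType, corMethod, power,
                    withQuality = FALSE) {
    .buildContext(Xref, Xtest, dataType = "expression",
                  networkType = networkType, corMethod = corMethod,
                  power = power, withClusterCoef = FALSE,
                  withQuality = withQuality)
}

#' Density preservation statistics for correlation networks
#'
#' For each proper module evaluates, in the test expression data:
#' `meanSignAwareCorDat`, the mean over module node pairs of the test
#' correlation multiplied by the sign of the corresponding reference
#' correlation (sign flips count against preservation);
#' `propVarExplained`, the proportion of module variance explained by the
#' test-data module eigennode, computed as the mean squared test kME over
#' module members; and `meanSignAwareKME`, the mean test kME signed by the
#' reference kME.
#'
#' @param Xref,Xtest Reference and test expression matrices
#'   (samples x nodes) over the same node universe.
#' @param labels Named module assignment.
#' @param networkType `"unsigned"` or `"signed"` (used for adjacency-based
#'   statistics and eigennode separability conventions).
#' @param corMethod Correlation estimator.
#' @param power Soft-thresholding power (default by `networkType`).
#' @param minModuleSize Modules smaller than this are skipped.
#' @return data.frame with one row per module.
#' @export
corDensityStats <- function(Xref, Xtest, labels,
                            networkType = c("unsigned", "signed"),
                            corMethod = "pearson", power = NULL,
                            minModuleSize = 3L) {
    networkType <- match.arg(networkType)
    ctx <- .corCtx(Xref, Xtest, networkType, corMethod, power)
    ms <- .moduleIndexSets(ctx, labels, minModuleSize, includeGrey = FALSE)
    M <- .evalModules(ctx, ms$idxList)
    data.frame(module = names(ms$idxList),
               moduleSize = lengths(ms$idxList),
               meanSignAwareCorDat = M[, "meanSignAwareCorDat"],
               propVarExplained = M[, "propVarExplained"],
               meanSignAwareKME = M[, "meanSignAwareKME"],
               row.names = NULL)
}

#' Connectivity preservation statistics for correlation networks
#'
#' For each proper module: `cor.cor`, the correlation between the
#' vectorized reference and test module correlation matrices; `cor.kME`,
#' the correlation of reference and test module memberships over module
#' members; and `cor.kMEall`, the same correlation over *all* network
#' nodes (less sensitive to how module boundaries were drawn, but noisier
#' for small modules).
#'
#' @inheritParams corDensityStats
#' @return data.frame with one row per module.
#' @export
corConnectivityStats <- function(Xref, Xtest, labels,
                                 networkType = c("unsigned", "signed"),
                                 corMethod = "pearson", power = NULL,
                                 minModuleSize = 3L) {
    networkType <- match.arg(networkType)
    ctx <- .corCtx(Xref, Xtest, networkType, corMethod, power)
    ms <- .moduleIndexSets(ctx, labels, minModuleSize, includeGrey = FALSE)
    M <- .evalModules(ctx, ms$idxList)
    data.frame(module = names(ms$idxList),
               moduleSize = lengths(ms$idxList),
               cor.cor = M[, "cor.cor"],
               cor.kME = M[, "cor.kME"],
               cor.kMEall = M[, "cor.kMEall"],
               row.names = NULL)
}

#' Eigennode-based module separability
#'
#' Pairwise separability of two modules is 1 minus the correlation of
#' their eigennodes; in unsigned runs the absolute correlation is used
#' (anti-correlated eigennodes count as connected, mirroring unsigned
#' adjacency logic), in signed runs the raw correlation. The per-module
#' summary is the minimum over the other proper modules.
#'
#' @param X Expression matrix on which eigennodes are computed.
#' @inheritParams corDensityStats
#' @return List with `pairwise` matrix and `perModule` vector.
#' @export
eigennodeSeparability <- function(X, labels,
                                  networkType = c("unsigned", "signed"),
                                  minModuleSize = 3L) {
    networkType <- match.arg(networkType)
    X <- .checkExpression(X)
    labels <- .normalizeLabels(labels, colnames(X))[colnames(X)]
    mods <- sort(setdiff(unique(labels), "grey"))
    mods <- mods[vapply(mods, function(q)
        sum(labels == q) >= minModuleSize, logical(1L))]
    if (length(mods) < 2L)
        stop("separability needs at least 2 proper modules")
    E <- vapply(mods, function(q)
        moduleEigennode(X[, labels == q, drop = FALSE])$eigennode,
        numeric(nrow(X)))
    cc <- suppressWarnings(stats::cor(E))
    pw <- if (networkType == "unsigned") 1 - abs(cc) else 1 - cc
    diag(pw) <- NA_real_
    dimnames(pw) <- list(mods, mods)
    perModule <- apply(pw, 1L, function(x)
        if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
    list(pairwise = pw, perModule = perModule)
}

#' Module quality statistics on a single (reference) network
#'
#' Density and separability statistics applied to the reference data alone
#' measure module *quality*: how tightly interconnected each module is and
#' how distinct it is from the others, without reference to a test
#' network. Reported per proper module: `quality.meanAdj` (module density
#' of the reference adjacency), `quality.propVarExplained` (PVE of the
#' reference eigennode), `quality.meanSignAwareKME` (mean absolute
#' reference kME; reference signs applied to themselves), and the two
#' separability statistics. Z statistics for quality are obtained through
#' [modulePreservation()], which permutes the reference labels with the
#' same permutation engine.
#'
#' @param Xref Reference expression matrix (samples x nodes), or a
#'   reference adjacency matrix with `dataType = "adjacency"`.
#' @inheritParams corDensityStats
#' @param dataType `"expression"` or `"adjacency"`.
#' @return data.frame with one row per module.
#' @export
qualityStats <- function(Xref, labels,
                         dataType = c("expression", "adjacency"),
                         networkType = c("unsigned", "signed"),
                         corMethod = "pearson", power = NULL,
                         minModuleSize = 3L) {
    dataType <- match.arg(dataType)
    networkType <- match.arg(networkType)
    ctx <- .buildContext(Xref, NULL, dataType = dataType,
                         networkType = networkType, corMethod = corMethod,
                         power = power, withClusterCoef = FALSE,
                         withQuality = TRUE)
    ms <- .moduleIndexSets(ctx, labels, minModuleSize, includeGrey = FALSE)
    M <- .evalModules(ctx, ms$idxList)
    out <- data.frame(module = names(ms$idxList),
                      moduleSize = lengths(ms$idxList),
                      row.names = NULL)
    cbind(out, as.data.frame(M, row.names = seq_len(nrow(M))))
}
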