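# Preservation statistics defined for any adjacency-specified network.

#' Density-based preservation statistics for a general network
#'
#' For each proper module, evaluates on the test network the module density
#' (`meanAdj`), the mean weighted clustering coefficient
#' (`meanClusterCoef`) and the mean maximum adjacency ratio (`meanMAR`),
#' all computed on the module sub-network. High values indicate that the
#' module's nodes remain densely interconnected in the test network.
#'
#' @param Atest Test-network adjacency matrix.
#' @param labels Named module assignment (node id -> label; `"0"`/`"grey"`
#'   mean unassigned).
#' @param minModuleSize Modules smaller than this are skipped with a
#'   warning.
#' @return data.frame with one row per module: `module`, `moduleSize`,
#'   `meanAdj`, `meanClusterCoef`, `meanMAR`.
#' @export
generalDensityStats <- function(Atest, labels, minModuleSize = 3L) {
    ctx <- .buildContext(Atest, Atest, dataType = "adjacency",
                         withQuality = FALSE)
    ms <- .moduleIndexSets(ctx, labels, minModuleSize, includeGrey = FALSE)
    M <- .evalModules(ctx, ms$idxList)
    data.frame(module = names(ms$idxList),
               moduleSize = lengths(ms$idxList),
               meanAdj = M[, "meanAdj"],
               meanClusterCoef = M[, "meanClusterCoef"],
               meanMAR = M[, "meanMAR"],
               row.names = NULL)
}

#' Connectivity-based preservation statistics for a general network
#'
#' For each proper module, correlates reference- and test-network
#' quantities: the vectorized module adjacencies (`cor.adj`), intramodular
#' connectivities (`cor.kIM`), clustering coefficients (`cor.cc`) and
#' maximum adjacency ratios (`cor.MAR`). Values near 1 indicate that the
#' module's internal connectivity pattern (which nodes are hubs, which
#' pairs are strongly connected) is reproduced in the test network.
#'
#' @param Aref Reference-network adjacency matrix (same nodes as `Atest`).
#' @inheritParams generalDensityStats
#' @return data.frame with `module`, `moduleSize`, `cor.adj`, `cor.kIM`,
#'   `cor.cc`, `cor.MAR`.
#' @export
generalConnectivityStats <- function(Aref, Atest, labels,
                                     minModuleSize = 3L) {
    ctx <- .buildContext(Aref, Atest, dataType = "adjacency",
                         withQuality = FALSE)
    ms <- .moduleIndexSets(ctx, labels, minModuleSize, includeGrey = FALSE)
    M <- .evalModules(ctx, ms$idxList)
    data.frame(module = names(ms$idxList),
               moduleSize = lengths(ms$idxList),
               cor.adj = M[, "cor.adj"],
               cor.kIM = M[, "cor.kIM"],
               cor.cc = M[, "cor.cc"],
               cor.MAR = M[, "cor.MAR"],
               row.names = NULL)
}

#' Adjacency-based module separability
#'
#' For every pair of proper modules, separability is 1 minus the mean
#' inter-modular adjacency divided by the geometric mean of the two module
#' densities. Values near 1 mean the modules are distinct; values near or
#' below 0 mean the modules blend into each other. The per-module summary
#' is the minimum over all other modules (the most stringent view).
#'
#' @inheritParams generalDensityStats
#' @param A Adjacency matrix on which separability is evaluated.
#' @return List with `pairwise` (module x module matrix) and `perModule`
#'   (named vector of minima).
#' @export
adjacencySeparability <- function(A, labels, minModuleSize = 3L) {
    ctx <- .buildContext(A, NULL, dataType = "adjacency",
                         withQuality = TRUE)
    ms <- .moduleIndexSets(ctx, labels, minModuleSize, includeGrey = FALSE)
    idxList <- ms$idxList
    if (length(idxList) < 2L)
        stop("separability needs at least 2 proper modules")
    dens <- vapply(idxList, function(idx)
        mean(vectorizeUpper(A[idx, idx, drop = FALSE]), na.rm = TRUE),
        numeric(1L))
    mods <- names(idxList)
    pw <- matrix(NA_real_, length(mods), length(mods),
                 dimnames = list(mods, mods))
    for (i in seq_along(mods)) {
        for (j in seq_along(mods)) {
            if (i == j) next
            d <- sqrt(dens[i] * dens[j])
            if (is.na(d) || d <= 0) next
            inter <- mean(A[idxList[[i]], idxList[[j]]], na.rm = TRUE)
            pw[i, j] <- 1 - inter / d
        }
    }
    perModule <- apply(pw, 1L, function(x)
        if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
    list(pairwise = pw, perModule = perModule)
}
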