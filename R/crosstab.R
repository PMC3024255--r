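# Cross-tabulation preservation statistics: these require module
# assignments in both networks (e.g. after independent module detection in
# the test data) and ignore the network adjacencies entirely.

# Align two labelings on their shared node universe (must be identical).
.alignLabels <- function(labelsRef, labelsTest) {
    labelsRef <- .normalizeLabels(labelsRef)
    labelsTest <- .normalizeLabels(labelsTest)
    if (!setequal(names(labelsRef), names(labelsTest)))
        stop("the two labelings must cover the same node universe; ",
             "offending nodes: ",
             paste(utils::head(c(
                 setdiff(names(labelsRef), names(labelsTest)),
                 setdiff(names(labelsTest), names(labelsRef))), 5L),
                 collapse = ", "))
    list(ref = labelsRef, test = labelsTest[names(labelsRef)])
}

#' Cross-tabulation of two module assignments
#'
#' Counts, for every (reference module, test module) pair, the nodes
#' carrying both labels. Cell sums equal the number of nodes.
#'
#' @param labelsRef,labelsTest Named module assignments over the same
#'   node universe.
#' @return Integer matrix, reference modules (rows) x test modules
#'   (columns).
#' @export
contingencyTable <- function(labelsRef, labelsTest) {
    al <- .alignLabels(labelsRef, labelsTest)
    tab <- table(reference = al$ref, test = al$test)
    mat <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                  dimnames = dimnames(tab))
    mat
}

#' Fisher overlap significance of a module pair
#'
#' Collapses the cross-tabulation to the 2x2 table (in/out of reference
#' module `q` vs in/out of test module `qTest`) and reports the one-sided
#' hypergeometric over-representation p-value as -log10 p. Symmetric in
#' the two modules.
#'
#' @inheritParams contingencyTable
#' @param q Reference module label.
#' @param qTest Test module label.
#' @return -log10 of the one-sided overlap p-value (`NA` for an empty
#'   module).
#' @export
fisherOverlapNegLogP <- function(labelsRef, labelsTest, q, qTest) {
    al <- .alignLabels(labelsRef, labelsTest)
    n <- length(al$ref)
    inQ <- al$ref == q
    inQt <- al$test == qTest
    K <- sum(inQ)
    s <- sum(inQt)
    if (K == 0L || s == 0L)
        return(NA_real_)
    a <- sum(inQ & inQt)
    # upper tail P(X >= a), X ~ Hypergeom(n, K, s), on the log scale
    lp <- stats::phyper(a - 1L, K, n - K, s, lower.tail = FALSE,
                        log.p = TRUE)
    -lp / log(10)
}

#' Co-clustering proportion of a reference module
#'
#' Among all node pairs co-assigned to reference module `q`, the fraction
#' that also share a common *proper* module label in the test assignment
#' (grey never counts as a common label). A value of 1 means the module's
#' nodes stay together in the test clustering; 0 means they scatter.
#'
#' @inheritParams contingencyTable
#' @param q Reference module label (at least 2 nodes).
#' @return Proportion in \[0, 1\]; `NA` for a singleton module.
#' @export
coClustering <- function(labelsRef, labelsTest, q) {
    al <- .alignLabels(labelsRef, labelsTest)
    testLab <- al$test[al$ref == q]
    nq <- length(testLab)
    if (nq < 2L)
        return(NA_real_)
    counts <- table(testLab[testLab != "grey"])
    together <- sum(counts * (counts - 1) / 2)
    together / (nq * (nq - 1) / 2)
}

#' Best-match overlap proportion of a reference module
#'
#' The accuracy-style cross-tabulation statistic: for reference module
#' `q`, the largest fraction of its nodes captured by any single proper
#' test module, `max_q' |q intersect q'| / |q|`.
#'
#' @inheritParams coClustering
#' @return Proportion in \[0, 1\].
#' @export
bestMatchOverlap <- function(labelsRef, labelsTest, q) {
    al <- .alignLabels(labelsRef, labelsTest)
    testLab <- al$test[al$ref == q]
    if (length(testLab) == 0L)
        return(NA_real_)
    proper <- testLab[testLab != "grey"]
    if (length(proper) == 0L)
        return(0)
    max(table(proper)) / length(testLab)
}

#' All cross-tabulation statistics for two labelings
#'
#' Convenience wrapper: the contingency table, the per-cell -log10 Fisher
#' overlap p-values, and per reference module the co-clustering and
#' best-match overlap proportions.
#'
#' @inheritParams contingencyTable
#' @return List with `counts`, `negLogP` (matrices) and `perModule`
#'   (data.frame).
#' @export
crossTabulation <- function(labelsRef, labelsTest) {
    counts <- contingencyTable(labelsRef, labelsTest)
    nlp <- counts * NA_real_
    for (q in rownames(counts))
        for (qt in colnames(counts))
            nlp[q, qt] <- fisherOverlapNegLogP(labelsRef, labelsTest, q, qt)
    refMods <- setdiff(rownames(counts), "grey")
    perModule <- data.frame(
        module = refMods,
        coClustering = vapply(refMods, function(q)
            coClustering(labelsRef, labelsTest, q), numeric(1L)),
        bestMatchOverlap = vapply(refMods, function(q)
            bestMatchOverlap(labelsRef, labelsTest, q), numeric(1L)),
        row.names = NULL)
    list(counts = counts, negLogP = nlp, perModule = perModule)
}
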