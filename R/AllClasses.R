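#' @import methods
NULL

#' ModulePreservation result container
#'
#' Holds the full output of a module-preservation run: the long-format
#' table of observed statistics with their permutation null moments, Z
#' statistics and log10 p-values; the per-module composite summaries
#' (Zdensity, Zconnectivity, Zsummary, medianRank, summary log10 p,
#' evidence call); optionally the raw permutation null samples; and run
#' metadata (seed, configuration, exclusions, undefined-statistic counts).
#'
#' @slot results data.frame, one row per (module, statistic).
#' @slot composites data.frame, one row per module.
#' @slot nulls list; per-statistic permutation null samples when requested.
#' @slot metadata list of run configuration and bookkeeping.
#'
#' @seealso [modulePreservation()], [preservationStats()],
#'   [compositeStats()]
#' @export
setClass("ModulePreservation",
         slots = c(results = "data.frame",
                   composites = "data.frame",
                   nulls = "list",
                   metadata = "list"))

setValidity("ModulePreservation", function(object) {
    msg <- character(0)
    need <- c("module", "moduleSize", "statistic", "observed")
    if (!all(need %in% names(object@results)))
        msg <- c(msg, paste("results must contain columns:",
                            paste(need, collapse = ", ")))
    cm <- object@composites
    if (all(c("Zdensity", "Zconnectivity", "Zsummary") %in% names(cm))) {
        ok <- stats::complete.cases(cm$Zdensity, cm$Zconnectivity,
                                    cm$Zsummary)
        if (any(ok) && max(abs(cm$Zsummary[ok] -
                (cm$Zdensity[ok] + cm$Zconnectivity[ok]) / 2)) > 1e-10)
            msg <- c(msg,
                "Zsummary must equal (Zdensity + Zconnectivity)/2")
    }
    if (length(msg)) msg else TRUE
})

#' SimulatedStudy container
#'
#' A paired reference/test synthetic co-expression study: two expression
#' matrices over an identical node universe, the module assignment, the
#' per-module preservation ground truth, and the scenario parameters
#' actually used.
#'
#' @slot refExpr Reference expression matrix (samples x nodes).
#' @slot testExpr Test expression matrix (samples x nodes).
#' @slot labels Named module assignment.
#' @slot truth data.frame: module, size, preservation type
#'   (`both`, `density_only`, `connectivity_only`, `none`) and a logical
#'   `preserved` flag.
#' @slot scenario list of generator parameters (scenario id, sizes,
#'   correlation range, samples, grey count, seed).
#'
#' @seealso [simulateScenario()]
#' @export
setClass("SimulatedStudy",
         slots = c(refExpr = "matrix",
                   testExpr = "matrix",
                   labels = "character",
                   truth = "data.frame",
                   scenario = "list"))

setValidity("SimulatedStudy", function(object) {
    msg <- character(0)
    if (!identical(colnames(object@refExpr), colnames(object@testExpr)))
        msg <- c(msg, "reference and test node universes must be identical")
    if (!identical(sort(names(object@labels)),
                   sort(colnames(object@refExpr))))
        msg <- c(msg, "labels must cover exactly the node universe")
    proper <- sort(setdiff(unique(object@labels), "grey"))
    if (!all(proper %in% object@truth$module))
        msg <- c(msg, "truth table must cover every proper module")
    if (length(msg)) msg else TRUE
})
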