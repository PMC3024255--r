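# Generics, accessors and show methods for the result containers.

#' Long-format preservation statistics of a run
#'
#' @param x A [ModulePreservation-class] object.
#' @return data.frame with one row per (module, statistic): observed value,
#'   permutation null mean and sd, Z, signed log10 p and Bonferroni-adjusted
#'   log10 p (when permutations were run).
#' @export
setGeneric("preservationStats", function(x) standardGeneric("preservationStats"))

#' @rdname preservationStats
#' @export
setMethod("preservationStats", "ModulePreservation", function(x) x@results)

#' Per-module composite summaries of a run
#'
#' @param x A [ModulePreservation-class] object.
#' @return data.frame with one row per module: Zdensity, Zconnectivity,
#'   Zsummary, the medianRank composites, summary log10 p and the evidence
#'   call ("strong", "weak to moderate", "none").
#' @export
setGeneric("compositeStats", function(x) standardGeneric("compositeStats"))

#' @rdname compositeStats
#' @export
setMethod("compositeStats", "ModulePreservation", function(x) x@composites)

#' Run metadata (seed, configuration, exclusions, undefined counts)
#'
#' @param x A [ModulePreservation-class] object.
#' @return Named list.
#' @export
setGeneric("runInfo", function(x) standardGeneric("runInfo"))

#' @rdname runInfo
#' @export
setMethod("runInfo", "ModulePreservation", function(x) x@metadata)

#' Permutation null samples (if kept at run time)
#'
#' @param x A [ModulePreservation-class] object.
#' @return List with a 3-d array `samples` (permutation x module x
#'   statistic), or an empty list when `returnNulls = FALSE`.
#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))

#' @rdname nullSamples
#' @export
setMethod("nullSamples", "ModulePreservation", function(x) x@nulls)

setMethod("show", "ModulePreservation", function(object) {
    md <- object@metadata
    cm <- object@composites
    cat("ModulePreservation run (", md$dataType, " input, ",
        md$networkType, " network)\n", sep = "")
    cat("  nodes: ", md$nNodes, "; modules evaluated: ", nrow(cm),
        " (incl. improper: ",
        paste(intersect(cm$module, c("grey", "gold")), collapse = ", "),
        ")\n", sep = "")
    cat("  permutations: ", md$nPermutations, "; seed: ", md$seed,
        "\n", sep = "")
    if ("evidence" %in% names(cm)) {
        tab <- table(factor(cm$evidence,
                            levels = c("strong", "weak to moderate", "none")))
        cat("  evidence of preservation: strong ", tab[["strong"]],
            ", weak to moderate ", tab[["weak to moderate"]],
            ", none ", tab[["none"]], "\n", sep = "")
    }
    utils::head(cm, 12L) |> print()
    invisible(object)
})

#' Accessors for SimulatedStudy objects
#'
#' @param x A [SimulatedStudy-class] object.
#' @return The reference/test expression matrix, the named module label
#'   vector, the per-module ground-truth table, or the scenario parameter
#'   list.
#' @name SimulatedStudy-accessors
NULL

#' @rdname SimulatedStudy-accessors
#' @export
setGeneric("refExpression", function(x) standardGeneric("refExpression"))
#' @rdname SimulatedStudy-accessors
#' @export
setMethod("refExpression", "SimulatedStudy", function(x) x@refExpr)

#' @rdname SimulatedStudy-accessors
#' @export
setGeneric("testExpression", function(x) standardGeneric("testExpression"))
#' @rdname SimulatedStudy-accessors
#' @export
setMethod("testExpression", "SimulatedStudy", function(x) x@testExpr)

#' @rdname SimulatedStudy-accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))
#' @rdname SimulatedStudy-accessors
#' @export
setMethod("moduleLabels", "SimulatedStudy", function(x) x@labels)

#' @rdname SimulatedStudy-accessors
#' @export
setGeneric("moduleTruth", function(x) standardGeneric("moduleTruth"))
#' @rdname SimulatedStudy-accessors
#' @export
setMethod("moduleTruth", "SimulatedStudy", function(x) x@truth)

#' @rdname SimulatedStudy-accessors
#' @export
setGeneric("scenarioInfo", function(x) standardGeneric("scenarioInfo"))
#' @rdname SimulatedStudy-accessors
#' @export
setMethod("scenarioInfo", "SimulatedStudy", function(x) x@scenario)

setMethod("show", "SimulatedStudy", function(object) {
    sc <- object@scenario
    cat("SimulatedStudy: scenario '", sc$scenario, "'\n", sep = "")
    cat("  ", nrow(object@refExpr), " samples x ", ncol(object@refExpr),
        " nodes per data set\n", sep = "")
    cat("  proper modules: ", nrow(object@truth), " (",
        sum(object@truth$preserved), " preserved); grey nodes: ",
        sum(object@labels == "grey"), "\n", sep = "")
    cat("  membership correlations in [", sc$minCor, ", ", sc$maxCor,
        "]; seed ", sc$seed, "\n", sep = "")
    invisible(object)
})
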