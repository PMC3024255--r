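# Permutation null distributions, Z statistics, composite summaries,
# median ranks, and summary p-values.

# Composite membership: which individual statistics feed the density and
# connectivity composites.
.corDensitySet <- c("meanSignAwareCorDat", "propVarExplained",
                    "meanSignAwareKME")
.corConnectivitySet <- c("cor.adj", "cor.kIM", "cor.cor", "cor.kME")
.generalDensitySet <- "meanAdj"
.generalConnectivitySet <- c("cor.adj", "cor.kIM")

.compositeSets <- function(networkClass) {
    if (networkClass == "correlation")
        list(density = .corDensitySet, connectivity = .corConnectivitySet)
    else
        list(density = .generalDensitySet,
             connectivity = .generalConnectivitySet)
}

#' Randomly permute a module assignment
#'
#' Returns a module label vector over the same nodes in which the multiset
#' of labels (including grey) is preserved but the assignment of labels to
#' nodes is a uniform random permutation. Uses the current RNG state
#' unless a seed is given.
#'
#' @param labels Named module assignment.
#' @param seed Optional integer seed for a reproducible permutation.
#' @return Permuted named label vector.
#' @export
permuteModuleLabels <- function(labels, seed = NULL) {
    perm <- function() {
        out <- labels
        out[] <- sample(labels)
        out
    }
    if (is.null(seed)) perm() else .withSeed(seed, perm())
}

#' Permutation Z statistic from null samples
#'
#' Standardizes an observed statistic against its permutation null:
#' `Z = (observed - nullMean) / nullSD`, with the null sd estimated with
#' divisor (number of valid samples - 1). Under no preservation Z is
#' approximately standard normal, so a one-sided upper-tail p-value is
#' attached; it is reported as a signed base-10 logarithm (`log10(p)`,
#' more negative = stronger preservation), computed on the log scale so
#' that astronomically small p-values do not underflow.
#'
#' @param observed Observed statistic value.
#' @param nullSamples Numeric vector of permutation null values
#'   (`NA`s are dropped and counted).
#' @return List with `nullMean`, `nullSD`, `Z`, `log10.p`, `nValid`.
#' @export
zStatistic <- function(observed, nullSamples) {
    x <- nullSamples[!is.na(nullSamples)]
    n <- length(x)
    if (is.na(observed) || n < 2L)
        return(list(nullMean = NA_real_, nullSD = NA_real_, Z = NA_real_,
                    log10.p = NA_real_, nValid = n))
    mu <- mean(x)
    sdev <- stats::sd(x)
    if (sdev == 0)
        return(list(nullMean = mu, nullSD = 0, Z = NA_real_,
                    log10.p = NA_real_, nValid = n))
    z <- (observed - mu) / sdev
    lp <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)
    list(nullMean = mu, nullSD = sdev, Z = z, log10.p = lp, nValid = n)
}

#' Composite Z statistics for one module
#'
#' Summarizes the per-statistic permutation Z values of a module. For
#' correlation networks `Zdensity` is the median over the sign-aware mean
#' correlation, PVE and sign-aware kME Zs, and `Zconnectivity` the median
#' over the adjacency, intramodular-connectivity, correlation-pattern and
#' kME correlation Zs; `Zsummary` is their mean. For general networks the
#' density composite is the mean-adjacency Z alone and the connectivity
#' composite the median of the adjacency and kIM correlation Zs
#' (`Zsummary.adj`). Missing components are dropped from the median with a
#' warning.
#'
#' @param z Named vector of per-statistic Z values for one module.
#' @param networkClass `"correlation"` or `"general"`.
#' @return List with `Zdensity`, `Zconnectivity`, `Zsummary`.
#' @export
compositeZ <- function(z, networkClass = c("correlation", "general")) {
    networkClass <- match.arg(networkClass)
    sets <- .compositeSets(networkClass)
    zd <- .medianDrop(z[sets$density], "density composite")
    zc <- .medianDrop(z[sets$connectivity], "connectivity composite")
    list(Zdensity = zd, Zconnectivity = zc,
         Zsummary = mean(c(zd, zc)))
}

#' Median-rank composite across modules
#'
#' A module-size-insensitive relative measure of preservation. For each
#' composite-feeding observed statistic, modules are ranked with rank 1 =
#' largest (most preserved) observed value; ties receive average ranks and
#' undefined values rank last. `medianRank.density` and
#' `medianRank.connectivity` are the medians of the ranks within the
#' density and connectivity sets, and `medianRank` is their mean. Lower
#' medianRank = relatively better preserved.
#'
#' @param observed Matrix of observed statistics, modules x statistics
#'   (proper modules only).
#' @param networkClass `"correlation"` or `"general"`.
#' @return data.frame: module, medianRank.density, medianRank.connectivity,
#'   medianRank.
#' @export
medianRank <- function(observed, networkClass = c("correlation", "general")) {
    networkClass <- match.arg(networkClass)
    if (nrow(observed) < 2L)
        stop("median ranks need at least 2 proper modules")
    sets <- .compositeSets(networkClass)
    rankOne <- function(x) rank(-x, ties.method = "average", na.last = TRUE)
    ranks <- apply(observed, 2L, rankOne)
    if (is.null(dim(ranks)))
        ranks <- matrix(ranks, nrow = nrow(observed),
                        dimnames = dimnames(observed))
    med <- function(set) {
        set <- intersect(set, colnames(observed))
        apply(ranks[, set, drop = FALSE], 1L, stats::median)
    }
    mrd <- med(sets$density)
    mrc <- med(sets$connectivity)
    data.frame(module = rownames(observed),
               medianRank.density = mrd,
               medianRank.connectivity = mrc,
               medianRank = (mrd + mrc) / 2,
               row.names = NULL)
}

#' Summary log10 p-value for one module
#'
#' The median of the signed log10 p-values over the same statistics that
#' feed Zsummary. More negative values indicate stronger preservation.
#' This is a descriptive summary (the median of log p-values), not the
#' p-value of Zsummary itself.
#'
#' @param log10p Named vector of per-statistic signed log10 p-values.
#' @param networkClass `"correlation"` or `"general"`.
#' @return Single numeric value.
#' @export
summaryLogP <- function(log10p, networkClass = c("correlation", "general")) {
    networkClass <- match.arg(networkClass)
    sets <- .compositeSets(networkClass)
    .medianDrop(log10p[c(sets$density, sets$connectivity)])
}

# Evidence-of-preservation call from Zsummary, per the recommended
# thresholds: > 10 strong, 2-10 weak to moderate, < 2 none.
.evidenceFlag <- function(z) {
    ifelse(is.na(z), NA_character_,
           ifelse(z > 10, "strong",
                  ifelse(z >= 2, "weak to moderate", "none")))
}
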