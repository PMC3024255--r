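# Internal helpers shared across the package.

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Turns a symmetric matrix into the vector of its n(n-1)/2 non-redundant
#' off-diagonal entries, taken from the strict upper triangle in row-major
#' order: (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). The diagonal is
#' excluded because it is fixed by convention (1 for adjacency and
#' correlation matrices).
#'
#' @param M A square (symmetric) numeric matrix.
#' @return Numeric vector of length `nrow(M) * (nrow(M) - 1) / 2`.
#' @examples
#' M <- matrix(c(1, .2, .4, .2, 1, .6, .4, .6, 1), 3, 3)
#' vectorizeUpper(M)  # 0.2 0.4 0.6
#' @export
vectorizeUpper <- function(M) {
    if (!is.matrix(M) || nrow(M) != ncol(M))
        stop("'M' must be a square matrix")
    # t(M)[lower.tri(.)] walks the upper triangle of M in row-major order
    t(M)[lower.tri(M)]
}

# Correlation that returns an undefined-marker (NA) instead of erroring or
# warning when one side has zero variance or too few complete pairs.
.safeCor <- function(x, y, method = "pearson") {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L)
        return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(NA_real_)
    stats::cor(x[ok], y[ok], method = method)
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
    withr::with_seed(seed, code)
}

.isImproper <- function(labels) labels %in% c("grey", "gold")

# Normalize a label vector: "0" and "grey" mean unassigned; "gold" is
# reserved for the internal random whole-network module.
.normalizeLabels <- function(labels, nodeIds = NULL) {
    nms <- names(labels)
    if (is.null(nms) && !is.null(nodeIds))
        nms <- nodeIds
    if (is.null(nms))
        stop("module labels must be named by node id")
    labels <- as.character(labels)
    names(labels) <- nms
    labels[labels %in% c("0", "")] <- "grey"
    if (any(labels == "gold"))
        stop("the module label 'gold' is reserved for the internal ",
             "random whole-network module")
    labels
}

# Median that tolerates missing components (dropped with optional warning).
.medianDrop <- function(x, what = NULL) {
    miss <- is.na(x)
    if (all(miss)) return(NA_real_)
    if (any(miss) && !is.null(what))
        warning("dropping ", sum(miss), " missing component(s) from the ",
                what, " median", call. = FALSE)
    stats::median(x[miss == FALSE])
}
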