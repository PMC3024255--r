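# Module eigennodes (eigengenes), module membership (kME), and the
# proportion of variance explained.

#' Module eigennode (eigengene) and proportion of variance explained
#'
#' The eigennode of a module is the first principal component of its
#' standardized profiles: the single sample-space vector that best
#' summarizes the module. Node profiles are standardized (mean 0, unit
#' sample variance with divisor m-1); nodes with missing entries are
#' mean-imputed first. The proportion of variance explained (PVE) is the
#' leading squared singular value over the total. The sign of the
#' eigennode is oriented so that its mean correlation with the module's
#' node profiles is non-negative (ties keep the decomposition's sign),
#' which makes sign-aware statistics reproducible.
#'
#' @param Xq Expression matrix restricted to one module
#'   (samples x module nodes), at least 3 samples and 3 nodes.
#' @return List with `eigennode` (unit-norm vector over samples), `pve`,
#'   and `flipped` (whether orientation reversed the decomposition's sign).
#' @export
moduleEigennode <- function(Xq) {
    Xq <- .checkExpression(Xq)
    if (nrow(Xq) < 3L || ncol(Xq) < 3L)
        stop("module must have at least 3 samples and 3 nodes")
    Xs <- .standardize(Xq)
    if (all(is.na(Xs)) || all(Xs == 0))
        stop("degenerate module: all profiles are constant")
    sv <- svd(Xs, nu = 1L, nv = 0L)
    E <- sv$u[, 1L]
    pve <- sv$d[1L]^2 / sum(sv$d^2)
    # orientation: mean correlation of E with the module profiles >= 0
    s <- mean(suppressWarnings(stats::cor(E, Xs)), na.rm = TRUE)
    flipped <- isTRUE(s < 0)
    if (flipped)
        E <- -E
    names(E) <- rownames(Xq)
    list(eigennode = E, pve = pve, flipped = flipped)
}

# Column standardization with mean imputation of missing entries.
.standardize <- function(X) {
    X <- apply(X, 2L, function(x) {
        if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
        x
    })
    Xs <- scale(X)
    # constant columns scale to NaN; they carry no signal
    Xs[, attr(Xs, "scaled:scale") == 0] <- 0
    Xs[is.na(Xs)] <- 0
    Xs
}

#' Module membership (kME) of every node with respect to an eigennode
#'
#' Correlates each node profile (any network node, not only module
#' members) with a module eigennode. High `|kME|` marks intramodular hub
#' nodes; the sign records whether a node follows or opposes the module's
#' summary profile.
#'
#' @param X Expression matrix (samples x nodes), same samples as `E`.
#' @param E Module eigennode over the same samples.
#' @return Named vector of correlations in \[-1, 1\]; `NA` for constant
#'   profiles.
#' @export
moduleMembership <- function(X, E) {
    X <- .checkExpression(X)
    if (nrow(X) != length(E))
        stop("eigennode must be defined over the same samples as 'X'")
    kme <- suppressWarnings(
        stats::cor(X, E, use = "pairwise.complete.obs"))[, 1L]
    names(kme) <- colnames(X)
    kme
}

# Fast internal eigennode for pre-standardized, complete data.
# Returns list(E = unit-norm oriented eigennode, pve).
.eigennodeScaled <- function(Xs) {
    sv <- svd(Xs, nu = 1L, nv = 0L)
    E <- sv$u[, 1L]
    # mean cor(E, column) has the sign of mean(crossprod) for unit-sd columns
    if (mean(crossprod(Xs, E)) < 0)
        E <- -E
    list(E = E, pve = sv$d[1L]^2 / sum(sv$d^2))
}

# Fast kME for pre-standardized complete data: cor(x_i, E) with centered,
# unit-norm E and unit-variance columns reduces to a cross product.
.kmeScaled <- function(Xs, E) {
    drop(crossprod(Xs, E)) / sqrt(nrow(Xs) - 1)
}
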