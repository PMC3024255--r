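# Correlation estimation, soft-threshold adjacency construction, and the
# network concepts (density, connectivity, MAR, clustering coefficient,
# intramodular connectivity) that every preservation statistic consumes.

#' Pairwise node correlations from an expression matrix
#'
#' Computes the node-by-node correlation matrix of an expression matrix
#' (samples in rows, nodes in columns). Missing values are handled
#' pairwise-complete; any node pair with fewer than 3 complete paired
#' observations yields `NA` (an undefined-marker). A constant node profile
#' has no defined correlation with anything: its row/column is `NA` and a
#' warning names the offending nodes.
#'
#' @param X Numeric matrix, samples x nodes, with column names as node ids.
#' @param method One of `"pearson"`, `"spearman"`, `"bicor"` (biweight
#'   midcorrelation; robust to outlying samples).
#' @return Symmetric correlation matrix (nodes x nodes), diagonal 1.
#' @seealso [toAdjacency()] to turn correlations into network adjacencies.
#' @export
computeCorrelation <- function(X, method = c("pearson", "spearman", "bicor")) {
    method <- match.arg(method)
    X <- .checkExpression(X)
    if (nrow(X) < 3L)
        stop("need at least 3 samples to estimate correlations")
    constant <- apply(X, 2L, function(x) {
        x <- x[!is.na(x)]
        length(x) == 0L || stats::sd(x) == 0
    })
    if (any(constant))
        warning("constant node profile(s), correlations undefined: ",
                paste(utils::head(colnames(X)[constant], 5L), collapse = ", "),
                if (sum(constant) > 5L) ", ...", call. = FALSE)
    if (method == "bicor") {
        C <- .bicorMatrix(X)
    } else {
        C <- suppressWarnings(
            stats::cor(X, method = method, use = "pairwise.complete.obs"))
    }
    if (anyNA(X)) {
        # enforce the >= 3 complete-pairs rule (cor() only needs 2)
        counts <- crossprod(!is.na(X))
        C[counts < 3L] <- NA_real_
    }
    C[constant, ] <- NA_real_
    C[, constant] <- NA_real_
    C <- (C + t(C)) / 2          # exact symmetry
    C[C > 1] <- 1
    C[C < -1] <- -1
    diag(C) <- 1
    C
}

# Biweight midcorrelation with a 9-MAD outlier cutoff. Columns with MAD = 0
# fall back to pearson-style standardization (with a warning). With missing
# values the matrix is computed per pair on complete observations.
.bicorMatrix <- function(X) {
    transform1 <- function(x) {
        med <- stats::median(x)
        madx <- stats::mad(x, constant = 1)
        if (madx == 0) {
            # degenerate spread: pearson fallback for this column
            ctr <- x - mean(x)
            return(list(v = ctr, fallback = TRUE))
        }
        u <- (x - med) / (9 * madx)
        w <- (1 - u^2)^2 * (abs(u) < 1)
        list(v = (x - med) * w, fallback = FALSE)
    }
    n <- ncol(X)
    if (!anyNA(X)) {
        tr <- lapply(seq_len(n), function(j) transform1(X[, j]))
        if (any(vapply(tr, `[[`, logical(1L), "fallback")))
            warning("bicor: zero MAD for some node(s); ",
                    "falling back to pearson for those columns",
                    call. = FALSE)
        V <- vapply(tr, function(t) {
            nrm <- sqrt(sum(t$v^2))
            if (nrm == 0) rep(NA_real_, nrow(X)) else t$v / nrm
        }, numeric(nrow(X)))
        C <- crossprod(V)
        dimnames(C) <- list(colnames(X), colnames(X))
        return(C)
    }
    # slow pairwise-complete path
    C <- matrix(NA_real_, n, n, dimnames = list(colnames(X), colnames(X)))
    for (i in seq_len(n)) {
        for (j in i:n) {
            ok <- stats::complete.cases(X[, i], X[, j])
            if (sum(ok) < 3L) next
            vi <- transform1(X[ok, i])$v
            vj <- transform1(X[ok, j])$v
            d <- sqrt(sum(vi^2)) * sqrt(sum(vj^2))
            C[i, j] <- C[j, i] <- if (d == 0) NA_real_ else sum(vi * vj) / d
        }
    }
    C
}

#' Soft-threshold adjacency from a correlation matrix
#'
#' Raises correlations to a soft-thresholding power to obtain a weighted
#' adjacency matrix. In an *unsigned* network `a_ij = |cor_ij|^beta`, so
#' strong negative correlations count as connections; in a *signed* network
#' `a_ij = ((1 + cor_ij)/2)^beta`, so negatively correlated nodes are
#' unconnected.
#'
#' @param C Symmetric correlation matrix.
#' @param mode `"unsigned"` or `"signed"`.
#' @param power Soft-thresholding power beta (> 0). Defaults to the
#'   community convention: 6 for unsigned, 12 for signed networks.
#' @return Adjacency matrix with entries in \[0, 1\] and unit diagonal.
#' @export
toAdjacency <- function(C, mode = c("unsigned", "signed"), power = NULL) {
    mode <- match.arg(mode)
    if (is.null(power))
        power <- if (mode == "signed") 12 else 6
    if (!is.numeric(power) || length(power) != 1L || is.na(power) || power <= 0)
        stop("'power' must be a single positive number")
    A <- if (mode == "unsigned") abs(C)^power else ((1 + C) / 2)^power
    A[A > 1] <- 1
    diag(A) <- 1
    A
}

#' Fundamental network concepts of a weighted network
#'
#' Computes, from an adjacency matrix, the network density (mean
#' off-diagonal adjacency), per-node connectivity `k_i = sum_j a_ij`,
#' maximum adjacency ratio `MAR_i = sum_j a_ij^2 / sum_j a_ij`, and the
#' weighted clustering coefficient
#' `cc_i = sum_{j != l} a_ij a_jl a_li / ((sum_j a_ij)^2 - sum_j a_ij^2)`
#' (sums over `j, l != i`). If module labels are supplied, per-node
#' intramodular connectivity (`kIM`, the connectivity within the node's own
#' module sub-network) and per-module densities are added.
#'
#' Isolated nodes (`k_i = 0`) get `NA` MAR and clustering coefficient. In
#' an unweighted (0/1) network MAR is identically 1 for connected nodes.
#'
#' @param A Adjacency matrix (symmetric, entries in \[0, 1\], diagonal 1).
#' @param labels Optional named module assignment covering the nodes of `A`.
#' @return List with elements `density`, `connectivity`, `mar`,
#'   `clusterCoef`, and (with labels) `kIM` and `moduleDensity`.
#' @export
networkConcepts <- function(A, labels = NULL) {
    A <- validateAdjacency(A)
    A0 <- A
    diag(A0) <- 0
    k <- rowSums(A0)
    sq <- rowSums(A0^2)
    mar <- ifelse(k > 0, sq / k, NA_real_)
    # diag(A0 %*% A0 %*% A0) counts weighted closed triples through each node
    num <- rowSums((A0 %*% A0) * A0)
    den <- k^2 - sq
    cc <- ifelse(den > 0, num / den, NA_real_)
    out <- list(density = mean(vectorizeUpper(A)),
                connectivity = k, mar = mar, clusterCoef = cc)
    if (!is.null(labels)) {
        labels <- .normalizeLabels(labels, rownames(A))
        labels <- labels[rownames(A)]
        kIM <- rep(NA_real_, nrow(A))
        names(kIM) <- rownames(A)
        mods <- setdiff(unique(labels), "grey")
        modDens <- numeric(0)
        for (q in mods) {
            idx <- which(labels == q)
            if (length(idx) < 3L) next
            sub <- A0[idx, idx]
            kIM[idx] <- rowSums(sub)
            modDens[q] <- mean(vectorizeUpper(A[idx, idx, drop = FALSE]))
        }
        out$kIM <- kIM
        out$moduleDensity <- modDens
    }
    out
}

#' Validate (and gently repair) an adjacency matrix
#'
#' Checks that a matrix is square, symmetric within a tolerance, has
#' entries in \[0, 1\] and a unit diagonal; asymmetries within tolerance are
#' symmetrized by averaging, the diagonal is forced to 1.
#'
#' @param A Candidate adjacency matrix.
#' @param tol Symmetry tolerance.
#' @return The validated adjacency matrix.
#' @export
validateAdjacency <- function(A, tol = 1e-8) {
    if (!is.matrix(A) || nrow(A) != ncol(A))
        stop("adjacency must be a square matrix")
    if (max(abs(A - t(A)), na.rm = TRUE) > tol)
        stop("adjacency is not symmetric (tolerance ", tol, ")")
    A <- (A + t(A)) / 2
    rng <- range(A, na.rm = TRUE)
    if (rng[1L] < -tol || rng[2L] > 1 + tol)
        stop("adjacency entries must lie in [0, 1]")
    A[A < 0] <- 0
    A[A > 1] <- 1
    diag(A) <- 1
    A
}

# Basic shape checks for an expression matrix (samples x nodes).
.checkExpression <- function(X) {
    if (!is.matrix(X))
        X <- as.matrix(X)
    if (!is.numeric(X))
        stop("expression data must be numeric")
    if (is.null(colnames(X)))
        colnames(X) <- paste0("node", seq_len(ncol(X)))
    if (anyDuplicated(colnames(X)))
        stop("duplicate node ids in expression matrix")
    X
}
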