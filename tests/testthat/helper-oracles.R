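# Independent brute-force oracles used across the test files. These are
# deliberately naive loop implementations, kept separate from the package
# code paths they check.

# Product-moment correlation of two vectors, written out elementwise.
oracleCorPair <- function(x, y) {
    mx <- sum(x) / length(x)
    my <- sum(y) / length(y)
    num <- sum((x - mx) * (y - my))
    den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
    num / den
}

# Full correlation matrix via the pairwise oracle.
oracleCorMatrix <- function(X) {
    n <- ncol(X)
    C <- diag(1, n)
    for (i in seq_len(n))
        for (j in seq_len(n))
            if (i != j) C[i, j] <- oracleCorPair(X[, i], X[, j])
    dimnames(C) <- list(colnames(X), colnames(X))
    C
}

# Network concepts by direct summation (triple loop for the clustering
# coefficient).
oracleConcepts <- function(A) {
    n <- nrow(A)
    k <- mar <- cc <- numeric(n)
    for (i in seq_len(n)) {
        others <- setdiff(seq_len(n), i)
        k[i] <- sum(A[i, others])
        mar[i] <- if (k[i] > 0) sum(A[i, others]^2) / k[i] else NA_real_
        num <- 0
        for (j in others)
            for (l in setdiff(others, j))
                num <- num + A[i, j] * A[j, l] * A[l, i]
        den <- k[i]^2 - sum(A[i, others]^2)
        cc[i] <- if (den > 0) num / den else NA_real_
    }
    dens <- 0
    for (i in seq_len(n - 1))
        for (j in (i + 1):n)
            dens <- dens + A[i, j]
    list(density = dens / (n * (n - 1) / 2), k = k, mar = mar, cc = cc)
}

# Upper-tail hypergeometric probability P(X >= a) by direct enumeration
# over choose() products.
oracleHyperTail <- function(n, K, s, a) {
    kk <- a:min(K, s)
    sum(choose(K, kk) * choose(n - K, s - kk)) / choose(n, s)
}

# PVE via a full spectral decomposition of the standardized module data
# (independent of the package's svd/kME route).
oraclePve <- function(Xq) {
    Xs <- scale(Xq)
    ev <- eigen(crossprod(Xs), symmetric = TRUE, only.values = TRUE)$values
    ev[1] / sum(ev)
}

# A small random expression fixture with named samples/nodes.
makeExpr <- function(m, n, seed = 1, prefix = "g") {
    withr::with_seed(seed, {
        X <- matrix(rnorm(m * n), m, n,
                    dimnames = list(paste0("s", seq_len(m)),
                                    paste0(prefix, seq_len(n))))
        X
    })
}

# A random valid adjacency fixture.
makeAdj <- function(n, seed = 1) {
    withr::with_seed(seed, {
        A <- matrix(runif(n * n), n, n)
        A <- (A + t(A)) / 2
        diag(A) <- 1
        dimnames(A) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
        A
    })
}

# Labels helper: named assignment from a vector of sizes.
makeLabels <- function(sizes, nodeIds, greyRest = TRUE) {
    lab <- rep(sprintf("M%02d", seq_along(sizes)), times = sizes)
    if (greyRest && length(lab) < length(nodeIds))
        lab <- c(lab, rep("grey", length(nodeIds) - length(lab)))
    names(lab) <- nodeIds
    lab
}

# A small multi-module expression fixture with controllable preservation.
makeCorStudy <- function(m = 40, sizes = c(10, 12), minCor = .6,
                         maxCor = .9, seed = 1, preserveAll = TRUE) {
    withr::with_seed(seed, {
        n <- sum(sizes)
        ids <- paste0("g", seq_len(n))
        lab <- makeLabels(sizes, ids, greyRest = FALSE)
        gen <- function(seeds) {
            X <- matrix(NA_real_, m, n, dimnames = list(NULL, ids))
            off <- 0
            for (q in seq_along(sizes)) {
                r <- seq(minCor, maxCor, length.out = sizes[q])
                noise <- matrix(rnorm(m * sizes[q]), m)
                X[, off + seq_len(sizes[q])] <-
                    outer(seeds[, q], r) + sweep(noise, 2, sqrt(1 - r^2), `*`)
                off <- off + sizes[q]
            }
            X
        }
        seeds <- matrix(rnorm(m * length(sizes)), m)
        Xref <- gen(seeds)
        Xtest <- if (preserveAll) gen(seeds)
                 else matrix(rnorm(m * n), m, dimnames = list(NULL, ids))
        list(Xref = Xref, Xtest = Xtest, labels = lab)
    })
}
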