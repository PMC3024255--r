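# Internal evaluation engine: builds the run context (correlations,
# adjacencies, standardized data) once, then evaluates every applicable
# observed statistic on arbitrary module node sets. The permutation null
# re-uses the same evaluator on permuted node sets, so observed and null
# values are computed by identical code paths.

.buildContext <- function(reference, test = NULL,
                          dataType = c("expression", "adjacency"),
                          networkType = c("unsigned", "signed"),
                          corMethod = c("pearson", "spearman", "bicor"),
                          power = NULL,
                          withClusterCoef = TRUE,
                          withQuality = TRUE) {
    dataType <- match.arg(dataType)
    networkType <- match.arg(networkType)
    corMethod <- match.arg(corMethod)
    if (is.null(power))
        power <- if (networkType == "signed") 12 else 6
    ctx <- list(dataType = dataType, networkType = networkType,
                corMethod = corMethod, power = power,
                withCC = withClusterCoef, withQuality = withQuality,
                withTest = !is.null(test))
    if (dataType == "expression") {
        Xref <- .checkExpression(reference)
        nodeIds <- colnames(Xref)
        ctx$Xref <- Xref
        ctx$corRef <- computeCorrelation(Xref, corMethod)
        ctx$Aref <- toAdjacency(ctx$corRef, networkType, power)
        ctx$XrefS <- .standardize(Xref)
        ctx$fastRef <- !anyNA(Xref)
        if (!is.null(test)) {
            Xtest <- .checkExpression(test)
            if (!setequal(colnames(Xtest), nodeIds))
                stop("reference and test data must share the same node ",
                     "universe; offending nodes: ",
                     paste(utils::head(c(
                         setdiff(nodeIds, colnames(Xtest)),
                         setdiff(colnames(Xtest), nodeIds)), 5L),
                         collapse = ", "))
            Xtest <- Xtest[, nodeIds, drop = FALSE]
            ctx$Xtest <- Xtest
            ctx$corTest <- computeCorrelation(Xtest, corMethod)
            ctx$Atest <- toAdjacency(ctx$corTest, networkType, power)
            ctx$XtestS <- .standardize(Xtest)
            ctx$fastTest <- !anyNA(Xtest)
        }
    } else {
        Aref <- validateAdjacency(reference)
        nodeIds <- rownames(Aref)
        if (is.null(nodeIds))
            nodeIds <- rownames(Aref) <- colnames(Aref) <-
                paste0("node", seq_len(nrow(Aref)))
        ctx$Aref <- Aref
        if (!is.null(test)) {
            Atest <- validateAdjacency(test)
            if (is.null(rownames(Atest)))
                rownames(Atest) <- colnames(Atest) <- nodeIds
            if (!setequal(rownames(Atest), nodeIds))
                stop("reference and test networks must share the same ",
                     "node universe")
            ctx$Atest <- Atest[nodeIds, nodeIds]
        }
    }
    ctx$nodeIds <- nodeIds
    ctx$n <- length(nodeIds)
    ctx$statNames <- .statNames(ctx)
    ctx
}

# The statistics the context can evaluate, in reporting order.
.statNames <- function(ctx) {
    s <- character(0)
    if (ctx$withTest) {
        s <- c(s, "meanAdj")
        if (ctx$withCC) s <- c(s, "meanClusterCoef", "meanMAR")
        s <- c(s, "cor.adj", "cor.kIM")
        if (ctx$withCC) s <- c(s, "cor.cc", "cor.MAR")
        if (ctx$dataType == "expression")
            s <- c(s, "meanSignAwareCorDat", "propVarExplained",
                   "meanSignAwareKME", "cor.cor", "cor.kME", "cor.kMEall",
                   "separability.ME")
        s <- c(s, "separability.adj")
    }
    if (ctx$withQuality) {
        s <- c(s, "quality.meanAdj", "quality.separability.adj")
        if (ctx$dataType == "expression")
            s <- c(s, "quality.propVarExplained", "quality.meanSignAwareKME",
                   "quality.separability.ME")
    }
    s
}

# Intramodular network concepts of one module sub-network.
.subConcepts <- function(S, withCC = TRUE) {
    S0 <- S
    diag(S0) <- 0
    S0[is.na(S0)] <- 0
    k <- rowSums(S0)
    out <- list(k = k)
    if (withCC) {
        sq <- rowSums(S0^2)
        out$mar <- ifelse(k > 0, sq / k, NA_real_)
        den <- k^2 - sq
        num <- rowSums((S0 %*% S0) * S0)
        out$cc <- ifelse(den > 0, num / den, NA_real_)
    }
    out
}

# Eigennode and all-node kME for one side ("ref" or "test") and node set.
.sideEigenKME <- function(ctx, side, idx) {
    if (side == "ref") {
        Xs <- ctx$XrefS; X <- ctx$Xref; fast <- ctx$fastRef
    } else {
        Xs <- ctx$XtestS; X <- ctx$Xtest; fast <- ctx$fastTest
    }
    if (fast) {
        e <- .eigennodeScaled(Xs[, idx, drop = FALSE])
        kme <- .kmeScaled(Xs, e$E)
    } else {
        e0 <- moduleEigennode(X[, idx, drop = FALSE])
        e <- list(E = e0$eigennode, pve = e0$pve)
        kme <- moduleMembership(X, e$E)
    }
    names(kme) <- ctx$nodeIds
    list(E = e$E, pve = e$pve, kme = kme)
}

# Evaluate every applicable statistic for a list of module node-index sets.
# `proper` flags modules that take part in separability pairs (grey and
# gold are excluded there). Returns modules x statistics matrix.
.evalModules <- function(ctx, idxList, proper = NULL) {
    mods <- names(idxList)
    if (is.null(proper))
        proper <- !(mods %in% c("grey", "gold"))
    names(proper) <- mods
    M <- matrix(NA_real_, length(mods), length(ctx$statNames),
                dimnames = list(mods, ctx$statNames))
    densTest <- densRef <- stats::setNames(rep(NA_real_, length(mods)), mods)
    Etest <- Eref <- vector("list", length(mods))
    names(Etest) <- names(Eref) <- mods
    isExpr <- ctx$dataType == "expression"

    for (mod in mods) {
        idx <- idxList[[mod]]
        asr <- ctx$Aref[idx, idx, drop = FALSE]
        uar <- vectorizeUpper(asr)
        densRef[mod] <- mean(uar, na.rm = TRUE)
        if (ctx$withQuality)
            M[mod, "quality.meanAdj"] <- densRef[mod]
        if (ctx$withTest) {
            ast <- ctx$Atest[idx, idx, drop = FALSE]
            uat <- vectorizeUpper(ast)
            densTest[mod] <- mean(uat, na.rm = TRUE)
            M[mod, "meanAdj"] <- densTest[mod]
            cr <- .subConcepts(asr, ctx$withCC)
            ct <- .subConcepts(ast, ctx$withCC)
            M[mod, "cor.adj"] <- .safeCor(uar, uat)
            M[mod, "cor.kIM"] <- .safeCor(cr$k, ct$k)
            if (ctx$withCC) {
                M[mod, "meanClusterCoef"] <- mean(ct$cc, na.rm = TRUE)
                M[mod, "meanMAR"] <- mean(ct$mar, na.rm = TRUE)
                M[mod, "cor.cc"] <- .safeCor(cr$cc, ct$cc)
                M[mod, "cor.MAR"] <- .safeCor(cr$mar, ct$mar)
            }
        }
        if (isExpr) {
            er <- .sideEigenKME(ctx, "ref", idx)
            Eref[[mod]] <- er$E
            if (ctx$withQuality) {
                M[mod, "quality.propVarExplained"] <- mean(er$kme[idx]^2,
                                                           na.rm = TRUE)
                M[mod, "quality.meanSignAwareKME"] <- mean(abs(er$kme[idx]),
                                                           na.rm = TRUE)
            }
            if (ctx$withTest) {
                csr <- ctx$corRef[idx, idx, drop = FALSE]
                cst <- ctx$corTest[idx, idx, drop = FALSE]
                ur <- vectorizeUpper(csr)
                ut <- vectorizeUpper(cst)
                M[mod, "meanSignAwareCorDat"] <- mean(sign(ur) * ut,
                                                      na.rm = TRUE)
                M[mod, "cor.cor"] <- .safeCor(ur, ut)
                et <- .sideEigenKME(ctx, "test", idx)
                Etest[[mod]] <- et$E
                M[mod, "propVarExplained"] <- mean(et$kme[idx]^2,
                                                   na.rm = TRUE)
                M[mod, "meanSignAwareKME"] <- mean(sign(er$kme[idx]) *
                                                   et$kme[idx], na.rm = TRUE)
                M[mod, "cor.kME"] <- .safeCor(er$kme[idx], et$kme[idx])
                M[mod, "cor.kMEall"] <- .safeCor(er$kme, et$kme)
            }
        }
    }

    pr <- mods[proper]
    if (length(pr) >= 2L) {
        if (ctx$withTest)
            M[pr, "separability.adj"] <-
                .adjSeparability(ctx$Atest, idxList[pr], densTest[pr])
        if (ctx$withQuality)
            M[pr, "quality.separability.adj"] <-
                .adjSeparability(ctx$Aref, idxList[pr], densRef[pr])
        if (isExpr) {
            if (ctx$withTest)
                M[pr, "separability.ME"] <-
                    .eigenSeparability(Etest[pr], ctx$networkType)
            if (ctx$withQuality)
                M[pr, "quality.separability.ME"] <-
                    .eigenSeparability(Eref[pr], ctx$networkType)
        }
    }
    M
}

# Per-module adjacency-based separability: 1 - meanInterAdj / geometric
# mean of the two module densities, minimized over the other modules.
.adjSeparability <- function(A, idxList, dens) {
    mods <- names(idxList)
    nm <- length(mods)
    sep <- matrix(NA_real_, nm, nm, dimnames = list(mods, mods))
    for (i in seq_len(nm - 1L)) {
        for (j in (i + 1L):nm) {
            d <- sqrt(dens[i] * dens[j])
            if (is.na(d) || d <= 0) next
            inter <- mean(A[idxList[[i]], idxList[[j]]], na.rm = TRUE)
            sep[i, j] <- sep[j, i] <- 1 - inter / d
        }
    }
    apply(sep, 1L, function(x) if (all(is.na(x))) NA_real_ else
        min(x, na.rm = TRUE))
}

# Per-module eigennode separability: 1 - |cor(E_q, E_q')| (unsigned runs)
# or 1 - cor(E_q, E_q') (signed runs), minimized over the other modules.
.eigenSeparability <- function(Elist, networkType) {
    keep <- !vapply(Elist, is.null, logical(1L))
    out <- stats::setNames(rep(NA_real_, length(Elist)), names(Elist))
    Elist <- Elist[keep]
    if (length(Elist) < 2L) return(out)
    Em <- do.call(cbind, Elist)
    cc <- suppressWarnings(stats::cor(Em))
    sep <- if (networkType == "unsigned") 1 - abs(cc) else 1 - cc
    diag(sep) <- NA_real_
    out[names(Elist)] <- apply(sep, 1L, function(x)
        if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
    out
}

# Resolve labels into module node-index sets (in node-id order), applying
# the minimum-size filter. Returns list(idxList, excluded, labels).
.moduleIndexSets <- function(ctx, labels, minModuleSize = 3L,
                             includeGrey = TRUE) {
    labels <- .normalizeLabels(labels, ctx$nodeIds)
    unknown <- setdiff(names(labels), ctx$nodeIds)
    if (length(unknown))
        stop("labels reference unknown node id(s): ",
             paste(utils::head(unknown, 5L), collapse = ", "))
    if (!all(ctx$nodeIds %in% names(labels)))
        stop("labels missing for nodes: ",
             paste(utils::head(setdiff(ctx$nodeIds, names(labels)), 5L),
                   collapse = ", "))
    labels <- labels[ctx$nodeIds]
    mods <- setdiff(unique(labels), "grey")
    mods <- mods[order(mods)]
    if (includeGrey && any(labels == "grey"))
        mods <- c(mods, "grey")
    idxList <- lapply(mods, function(q) which(labels == q))
    names(idxList) <- mods
    sizes <- lengths(idxList)
    excluded <- mods[sizes < minModuleSize]
    if (length(excluded))
        warning("excluding module(s) smaller than ", minModuleSize,
                " nodes: ", paste(excluded, collapse = ", "), call. = FALSE)
    list(idxList = idxList[sizes >= minModuleSize],
         excluded = excluded, labels = labels)
}
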