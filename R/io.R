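# TSV input/output. Expression files: header row = node ids, first column
# = sample ids. Adjacency files: square, header row and first column both
# node ids. Label files: two columns, node id and module label.

#' Read an expression matrix from TSV
#'
#' @param path TSV file: header row of node ids, first column of sample
#'   ids, tab-separated numeric values.
#' @return Numeric matrix (samples x nodes).
#' @export
readExpression <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    sampleIds <- as.character(df[[1L]])
    M <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(M)) {
        bad <- which(!vapply(df[-1L], is.numeric, logical(1L)))[1L]
        stop("non-numeric values in column ", bad + 1L, " ('",
             names(df)[bad + 1L], "') of ", path)
    }
    rownames(M) <- sampleIds
    if (anyDuplicated(colnames(M)))
        stop("duplicate node ids in ", path)
    M
}

#' Write an expression matrix to TSV
#'
#' Round-trips through [readExpression()] with values preserved to 10
#' significant digits.
#'
#' @param X Numeric matrix (samples x nodes).
#' @param path Output file.
#' @export
writeExpression <- function(X, path) {
    df <- data.frame(sample = rownames(X),
                     signif(X, 10L), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read an adjacency matrix from TSV
#'
#' Validates symmetry within `tol` (then symmetrizes by averaging) and
#' the \[0, 1\] entry range; the diagonal is forced to 1.
#'
#' @param path Square TSV: header row and first column both node ids.
#' @param tol Symmetry tolerance.
#' @return Adjacency matrix.
#' @export
readAdjacency <- function(path, tol = 1e-8) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    M <- as.matrix(df[, -1L, drop = FALSE])
    rownames(M) <- ids
    if (!identical(rownames(M), colnames(M)))
        stop("adjacency row and column node ids differ in ", path)
    validateAdjacency(M, tol)
}

#' Write an adjacency matrix to TSV
#' @param A Adjacency matrix.
#' @param path Output file.
#' @export
writeAdjacency <- function(A, path) {
    df <- data.frame(node = rownames(A), signif(A, 10L),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a module assignment from TSV
#'
#' Two columns: node id and module label. Labels `"0"` and `"grey"` both
#' parse as unassigned; `"gold"` is reserved and rejected.
#'
#' @param path Label TSV (with header).
#' @return Named character vector of labels.
#' @export
readLabels <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2L)
        stop("label file must have node and label columns: ", path)
    if (anyDuplicated(df[[1L]]))
        stop("duplicate node ids in ", path)
    .normalizeLabels(stats::setNames(df[[2L]], df[[1L]]))
}

#' Write a module assignment to TSV
#' @param labels Named label vector.
#' @param path Output file.
#' @export
writeLabels <- function(labels, path) {
    utils::write.table(data.frame(node = names(labels),
                                  module = as.character(labels)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write the result tables of a preservation run
#'
#' Writes `<prefix>_results.tsv` (long format: one row per module and
#' statistic), `<prefix>_composites.tsv` (one row per module) and
#' `<prefix>_metadata.yaml` (seed, configuration, exclusions, undefined
#' counts). Undefined markers are serialized as `NA`. With the same
#' configuration and seed the files are byte-identical across runs.
#'
#' @param mp A [ModulePreservation-class] object.
#' @param prefix Output path prefix.
#' @return The three file paths, invisibly.
#' @export
writePreservation <- function(mp, prefix) {
    stopifnot(methods::is(mp, "ModulePreservation"))
    fmt <- function(df) {
        num <- vapply(df, is.numeric, logical(1L))
        df[num] <- lapply(df[num], function(x) signif(x, 10L))
        df
    }
    paths <- paste0(prefix, c("_results.tsv", "_composites.tsv",
                              "_metadata.yaml"))
    utils::write.table(fmt(preservationStats(mp)), paths[1L], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fmt(compositeStats(mp)), paths[2L], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    md <- runInfo(mp)
    md$packageVersion <- as.character(utils::packageVersion("netpreserve"))
    yaml::write_yaml(md, paths[3L])
    invisible(paths)
}

#' Run a preservation analysis from a configuration
#'
#' File-level driver around [modulePreservation()]: reads the reference
#' and test inputs and the module labels, runs the analysis, and writes
#' the result tables via [writePreservation()]. The configuration is a
#' named list (or a YAML file path) with fields `reference`, `test`,
#' `modules` (file paths), `data_type` (`expression`/`adjacency`),
#' `network` (`unsigned`/`signed`), `correlation`, `power`, `nperm`,
#' `seed`, `gold_size`, `min_module_size`, `out_prefix`.
#'
#' @param config Named list or path to a YAML file.
#' @return The [ModulePreservation-class] object, invisibly.
#' @export
runPreservation <- function(config) {
    if (is.character(config))
        config <- yaml::read_yaml(config)
    get <- function(key, default) {
        if (!is.null(config[[key]])) config[[key]] else default
    }
    dataType <- get("data_type", "expression")
    reader <- if (dataType == "expression") readExpression else readAdjacency
    reference <- reader(config$reference)
    test <- reader(config$test)
    labels <- readLabels(config$modules)
    mp <- modulePreservation(
        reference, test, labels,
        dataType = dataType,
        networkType = get("network", "unsigned"),
        corMethod = get("correlation", "pearson"),
        power = get("power", NULL),
        nPermutations = as.integer(get("nperm", 100L)),
        seed = as.integer(get("seed", 1L)),
        goldSize = as.integer(get("gold_size", 1000L)),
        minModuleSize = as.integer(get("min_module_size", 3L)),
        verbose = isTRUE(get("verbose", FALSE)))
    prefix <- get("out_prefix", NULL)
    if (!is.null(prefix))
        writePreservation(mp, prefix)
    invisible(mp)
}

#' Write a simulated study to the standard TSV files
#'
#' Emits `<prefix>_reference.tsv`, `<prefix>_test.tsv`,
#' `<prefix>_modules.tsv` and `<prefix>_truth.tsv`, consumable unchanged
#' by [runPreservation()].
#'
#' @param sim A [SimulatedStudy-class] object.
#' @param prefix Output path prefix.
#' @return The four file paths, invisibly.
#' @export
writeSimulatedStudy <- function(sim, prefix) {
    stopifnot(methods::is(sim, "SimulatedStudy"))
    paths <- paste0(prefix, c("_reference.tsv", "_test.tsv",
                              "_modules.tsv", "_truth.tsv"))
    writeExpression(refExpression(sim), paths[1L])
    writeExpression(testExpression(sim), paths[2L])
    writeLabels(moduleLabels(sim), paths[3L])
    utils::write.table(moduleTruth(sim), paths[4L], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(paths)
}
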