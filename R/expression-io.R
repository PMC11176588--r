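#' Construct a StateExpression object
#'
#' @param values numeric matrix of log2-scale expression, genes in rows
#'   (unique rownames), samples in columns (colnames).
#' @param state character vector, one of `"normal"`/`"tumor"` per sample.
#' @param datasetId dataset identifier stored in the object metadata.
#' @return A [StateExpression-class] object.
#' @examples
#' m <- matrix(rnorm(20, 7), 5, 4,
#'             dimnames = list(paste0("G", 1:5), paste0("S", 1:4)))
#' StateExpression(m, c("normal", "normal", "tumor", "tumor"), "toy")
#' @export
StateExpression <- function(values, state, datasetId) {
    if (length(state) != ncol(values))
        stopf("length of 'state' (%d) does not match sample count (%d)",
              length(state), ncol(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(state = as.character(state),
                                       row.names = colnames(values)))
    S4Vectors::metadata(se)$dataset_id <- as.character(datasetId)
    se <- methods::as(se, "StateExpression")
    methods::validObject(se)
    se
}

#' Expression values of a StateExpression
#'
#' @param x a [StateExpression-class].
#' @param state optional state label; when given, only samples of that state
#'   are returned.
#' @return Numeric matrix, genes in rows.
#' @export
exprValues <- function(x, state = NULL) {
    m <- SummarizedExperiment::assay(x, "exprs")
    if (!is.null(state)) m <- m[, stateLabels(x) == state, drop = FALSE]
    m
}

#' Read a tab-separated expression matrix with state labels
#'
#' Reads a genes-by-samples matrix (first column gene symbols, header row
#' sample ids) and attaches state labels from a sample-to-state map.
#' Duplicate gene rows are collapsed by their mean, with a message recording
#' the collapse.
#'
#' @param path path to the tab-separated matrix.
#' @param stateMap named character vector mapping sample id to
#'   `"normal"`/`"tumor"`, or a two-column data.frame (sample, state).
#' @param datasetId dataset identifier; defaults to the file name.
#' @return A [StateExpression-class].
#' @export
readExpression <- function(path, stateMap, datasetId = basename(path)) {
    raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 2) stopf("expression file '%s' has no sample columns", path)
    genes <- as.character(raw[[1]])
    m <- as.matrix(raw[, -1, drop = FALSE])
    bad <- which(!is.finite(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    if (length(bad)) {
        stopf("non-numeric value at gene '%s', sample '%s' in '%s'",
              genes[bad[1, 1]], colnames(m)[bad[1, 2]], path)
    }
    storage.mode(m) <- "double"
    if (is.data.frame(stateMap)) {
        stateMap <- stats::setNames(as.character(stateMap[[2]]),
                                    as.character(stateMap[[1]]))
    }
    missing <- setdiff(colnames(m), names(stateMap))
    if (length(missing))
        stopf("samples without state label: %s", paste(missing, collapse = ", "))
    if (anyDuplicated(genes)) {
        ndup <- sum(duplicated(genes))
        m <- rowsum(m, genes) / as.vector(table(genes)[sort(unique(genes))])
        message(sprintf("collapsed %d duplicate gene rows by mean", ndup))
    } else {
        rownames(m) <- genes
        m <- m[order(rownames(m)), , drop = FALSE]
    }
    StateExpression(m, unname(stateMap[colnames(m)]), datasetId)
}

#' Restrict datasets to their common genes
#'
#' Restricts every dataset to the sorted intersection of all gene sets, so
#' that downstream consensus operations see one shared gene universe.
#'
#' @param datasets list of [StateExpression-class] objects.
#' @return List of [StateExpression-class] objects over the common genes.
#' @export
intersectGenes <- function(datasets) {
    if (!length(datasets)) stopf("at least one dataset is required")
    common <- Reduce(intersect, lapply(datasets, rownames))
    if (!length(common)) stopf("gene intersection across datasets is empty")
    common <- sort(common)
    lapply(datasets, function(ds) ds[common, ])
}

#' Differential expression between tumor and normal states
#'
#' Per-gene log2 fold change (tumor mean minus normal mean on log2 values)
#' with a two-sided Welch t-test p-value. The Welch test is the package's
#' documented differential-expression test on already-normalised log2
#' matrices; externally computed tables can be supplied wherever a DE table
#' is consumed (columns `gene`, `log2fc`, `p_value`).
#'
#' @param ds a [StateExpression-class] with at least two samples per state.
#' @return data.frame with columns `gene`, `log2fc`, `p_value`.
#' @examples
#' m <- cbind(matrix(rnorm(40, 7), 10), matrix(rnorm(40, 8), 10))
#' dimnames(m) <- list(paste0("G", 1:10), paste0("S", 1:8))
#' ds <- StateExpression(m, rep(c("normal", "tumor"), each = 4), "toy")
#' head(differentialExpression(ds))
#' @export
differentialExpression <- function(ds) {
    st <- stateLabels(ds)
    if (sum(st == "normal") < 2 || sum(st == "tumor") < 2)
        stopf("differential expression needs >=2 samples per state (normal=%d, tumor=%d)",
              sum(st == "normal"), sum(st == "tumor"))
    tum <- exprValues(ds, "tumor")
    nor <- exprValues(ds, "normal")
    w <- welchRows(tum, nor)
    data.frame(gene = rownames(ds), log2fc = unname(w$estimate),
               p_value = unname(w$p), stringsAsFactors = FALSE)
}

#' Signature genes consistent across datasets
#'
#' Keeps genes from `genePool` that are significant (`p_value < pMax`) in
#' every dataset and whose mean log2 fold change across datasets has
#' magnitude at least `lfcMin`; the sign of the mean assigns the gene to the
#' up- or down-regulated set.
#'
#' @param deTables list of DE tables (columns `gene`, `log2fc`, `p_value`),
#'   one per dataset.
#' @param lfcMin minimum absolute mean log2 fold change (default 0.5).
#' @param pMax per-dataset p-value threshold (default 0.01).
#' @param genePool genes eligible for selection (must be covered by every
#'   table).
#' @return list with character vectors `up` and `down`.
#' @export
signatureGenes <- function(deTables, lfcMin = 0.5, pMax = 0.01, genePool) {
    if (!length(genePool)) stopf("genePool is empty")
    for (tab in deTables) {
        if (!all(genePool %in% tab$gene))
            stopf("genePool contains genes absent from a DE table")
    }
    lfc <- sapply(deTables, function(tab) tab$log2fc[match(genePool, tab$gene)])
    pv <- sapply(deTables, function(tab) tab$p_value[match(genePool, tab$gene)])
    lfc <- matrix(lfc, nrow = length(genePool))
    pv <- matrix(pv, nrow = length(genePool))
    meanLfc <- rowMeans(lfc)
    keep <- apply(pv < pMax, 1, all) & abs(meanLfc) >= lfcMin
    list(up = genePool[keep & meanLfc > 0], down = genePool[keep & meanLfc < 0])
}
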