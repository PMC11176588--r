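#' Accessors for xtalknet classes
#'
#' `edgeTable()` returns the edge list of a network-like object;
#' `networkState()` the state label; `datasetIds()` the contributing dataset
#' identifiers; `geneSets()`, `pathwayCategories()` the contents of a
#' [PathwayCollection]; `pathGeNet()` the interface gene network of a
#' [CrosstalkNetwork]; `geneScores()` the per-gene table of a
#' [DysregulationResult]; `riskScores()` and `riskGroups()` the per-sample
#' values of a [RiskModel].
#'
#' @param x an xtalknet object.
#' @return A data.frame, character vector or named numeric, depending on the
#'   accessor.
#' @name accessors
#' @aliases edgeTable networkState datasetIds geneSets pathwayCategories
#'   pathGeNet geneScores riskScores riskGroups stateLabels datasetId
#' @examples
#' se <- StateExpression(matrix(rnorm(12), 3, 4,
#'                              dimnames = list(paste0("G", 1:3), paste0("S", 1:4))),
#'                       state = c("normal", "normal", "tumor", "tumor"),
#'                       datasetId = "toy")
#' stateLabels(se)
NULL

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("networkState", function(x) standardGeneric("networkState"))

#' @rdname accessors
#' @export
setGeneric("datasetIds", function(x) standardGeneric("datasetIds"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("pathwayCategories", function(x) standardGeneric("pathwayCategories"))

#' @rdname accessors
#' @export
setGeneric("pathGeNet", function(x) standardGeneric("pathGeNet"))

#' @rdname accessors
#' @export
setGeneric("geneScores", function(x) standardGeneric("geneScores"))

#' @rdname accessors
#' @export
setGeneric("riskScores", function(x) standardGeneric("riskScores"))

#' @rdname accessors
#' @export
setGeneric("riskGroups", function(x) standardGeneric("riskGroups"))

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname accessors
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname accessors
setMethod("edgeTable", "CoexpressionNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("edgeTable", "CrosstalkNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("edgeTable", "DirectedGRN", function(x) x@edges)

#' @rdname accessors
setMethod("networkState", "CoexpressionNetwork", function(x) x@state)

#' @rdname accessors
setMethod("networkState", "CrosstalkNetwork", function(x) x@state)

#' @rdname accessors
setMethod("datasetIds", "CoexpressionNetwork", function(x) x@datasetIds)

#' @rdname accessors
setMethod("geneSets", "PathwayCollection", function(x) x@sets)

#' @rdname accessors
setMethod("pathwayCategories", "PathwayCollection", function(x) x@categories)

#' @rdname accessors
setMethod("pathGeNet", "CrosstalkNetwork", function(x) x@pathGeNet)

#' @rdname accessors
setMethod("geneScores", "DysregulationResult", function(x) x@geneTable)

#' @rdname accessors
setMethod("edgeTable", "DysregulationResult", function(x) x@edgeTable)

#' @rdname accessors
setMethod("riskScores", "RiskModel", function(x) x@scores)

#' @rdname accessors
setMethod("riskGroups", "RiskModel", function(x) x@groups)

#' @rdname accessors
setMethod("stateLabels", "StateExpression", function(x)
    as.character(SummarizedExperiment::colData(x)$state))

#' @rdname accessors
setMethod("datasetId", "StateExpression", function(x)
    S4Vectors::metadata(x)$dataset_id)

setMethod("show", "StateExpression", function(object) {
    st <- table(stateLabels(object))
    cat(sprintf("StateExpression '%s': %d genes x %d samples (%s)\n",
                datasetId(object), nrow(object), ncol(object),
                paste(sprintf("%s=%d", names(st), st), collapse = ", ")))
})

setMethod("show", "CoexpressionNetwork", function(object) {
    cat(sprintf(
        "CoexpressionNetwork [%s]: %d edges, %d genes (|r|>=%g, p<%g; datasets: %s)\n",
        object@state, nrow(object@edges),
        length(unique(c(object@edges$gene_a, object@edges$gene_b))),
        object@rMin, object@pMax, paste(object@datasetIds, collapse = ",")))
})

setMethod("show", "PathwayCollection", function(object) {
    cat(sprintf("PathwayCollection: %d pathways, %d distinct genes\n",
                length(object@sets), length(unique(unlist(object@sets)))))
})

setMethod("show", "CrosstalkNetwork", function(object) {
    cat(sprintf(
        "CrosstalkNetwork [%s]: %d cross-talks among %d pathways; PathGeNet %d edges / %d genes\n",
        object@state, nrow(object@edges), length(object@nodes),
        nrow(object@pathGeNet),
        length(unique(c(object@pathGeNet$gene_a, object@pathGeNet$gene_b)))))
})

setMethod("show", "DirectedGRN", function(object) {
    cat(sprintf("DirectedGRN: %d directed edges among %d genes\n",
                nrow(object@edges), length(object@genes)))
})

setMethod("show", "DysregulationResult", function(object) {
    cat(sprintf(
        "DysregulationResult '%s': %d scored genes, %d measurable edges (%d significant at p<%g)\n",
        object@datasetId, nrow(object@geneTable), nrow(object@edgeTable),
        sum(object@edgeTable$significant), object@sigP))
})

setMethod("show", "RiskModel", function(object) {
    cat(sprintf(
        "RiskModel: %d genes, %d samples (high=%d, low=%d), median threshold %.4g\n",
        length(object@genes), length(object@scores),
        sum(object@groups == "high"), sum(object@groups == "low"),
        object@threshold))
})
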