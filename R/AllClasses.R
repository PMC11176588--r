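#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats cor pt pchisq phyper p.adjust median sd rnorm runif rexp
#' @importFrom utils read.delim write.table head
NULL

STATE_LEVELS <- c("normal", "tumor")

#' StateExpression: a state-labelled expression dataset
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' log2-scale expression matrix (genes in rows, samples in columns), a
#' per-sample state label (`"normal"` or `"tumor"`) in `colData(x)$state`,
#' and a dataset identifier in the object metadata.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @seealso [StateExpression()], [stateLabels()], [datasetId()]
#' @export
setClass("StateExpression", contains = "SummarizedExperiment")

setValidity("StateExpression", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        m <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(m) || any(!is.finite(m)))
            msg <- c(msg, "expression values must be finite numerics")
    }
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "gene symbols must be present and unique")
    st <- SummarizedExperiment::colData(object)$state
    if (is.null(st) || !all(st %in% STATE_LEVELS))
        msg <- c(msg, "colData(x)$state must be 'normal' or 'tumor' for every sample")
    if (is.null(S4Vectors::metadata(object)$dataset_id))
        msg <- c(msg, "metadata dataset_id is required")
    if (length(msg)) msg else TRUE
})

#' Undirected state-specific co-expression network
#'
#' Edge list of gene pairs passing a Pearson correlation and significance
#' threshold within one state. Pairs are stored canonically
#' (`gene_a < gene_b`); the provenance records the datasets and thresholds
#' that produced the edges.
#'
#' @slot edges data.frame with columns `gene_a`, `gene_b`, `r`, `p_value`.
#' @slot state `"normal"` or `"tumor"`.
#' @slot datasetIds character, datasets contributing to the edges.
#' @slot rMin,pMax thresholds used.
#' @export
setClass("CoexpressionNetwork",
    representation(edges = "data.frame", state = "character",
                   datasetIds = "character", rMin = "numeric", pMax = "numeric"))

setValidity("CoexpressionNetwork", function(object) {
    e <- object@edges
    msg <- character()
    need <- c("gene_a", "gene_b", "r", "p_value")
    if (!all(need %in% names(e)))
        return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
    if (nrow(e)) {
        if (any(e$gene_a >= e$gene_b))
            msg <- c(msg, "edges must be canonically ordered with gene_a < gene_b")
        if (anyDuplicated(paste(e$gene_a, e$gene_b)))
            msg <- c(msg, "duplicate gene pairs")
        if (any(abs(e$r) > 1 + 1e-12))
            msg <- c(msg, "|r| must not exceed 1")
    }
    if (!object@state %in% STATE_LEVELS)
        msg <- c(msg, "state must be 'normal' or 'tumor'")
    if (length(msg)) msg else TRUE
})

#' Collection of pathway gene sets
#'
#' Named gene sets (as read from a GMT file) with optional per-pathway
#' descriptions and category labels.
#'
#' @slot sets named list of character vectors (upper-cased gene symbols).
#' @slot descriptions named character, one per pathway.
#' @slot categories named character, optional category per pathway.
#' @export
setClass("PathwayCollection",
    representation(sets = "list", descriptions = "character",
                   categories = "character"))

setValidity("PathwayCollection", function(object) {
    msg <- character()
    ids <- names(object@sets)
    if (length(object@sets)) {
        if (is.null(ids) || anyDuplicated(ids))
            msg <- c(msg, "pathway ids must be unique and named")
        if (any(!vapply(object@sets, length, 1L)))
            msg <- c(msg, "gene sets must be non-empty")
    }
    if (length(msg)) msg else TRUE
})

#' Pathway cross-talk network with interface gene network
#'
#' Pathway-pair edges, each backed by co-expressed gene-pair evidence under
#' criterion (i) (two or more bridging pairs of exclusive genes) or criterion
#' (ii) (a shared gene co-expressed into both exclusive sides), together with
#' the induced interface gene co-expression network (PathGeNet).
#'
#' @slot edges data.frame: `pathway_a`, `pathway_b`, `criterion`,
#'   `n_support_pairs`.
#' @slot evidence named list (one entry per pathway pair) of data.frames with
#'   the supporting gene pairs and their roles.
#' @slot pathGeNet data.frame of the gene pairs supporting at least one
#'   cross-talk edge.
#' @slot nodes pathway ids with at least one cross-talk edge.
#' @slot state state label inherited from the co-expression network.
#' @export
setClass("CrosstalkNetwork",
    representation(edges = "data.frame", evidence = "list",
                   pathGeNet = "data.frame", nodes = "character",
                   state = "character"))

setValidity("CrosstalkNetwork", function(object) {
    e <- object@edges
    msg <- character()
    if (nrow(e)) {
        if (any(e$pathway_a == e$pathway_b)) msg <- c(msg, "self cross-talk edge")
        if (any(e$pathway_a >= e$pathway_b))
            msg <- c(msg, "pathway pairs must be canonically ordered")
    }
    if (length(msg)) msg else TRUE
})

#' Directed gene regulatory network
#'
#' Regulator -> target edge list with an optional interaction label.
#' Self-loops are forbidden and duplicate directed edges are collapsed at
#' construction.
#'
#' @slot edges data.frame: `regulator`, `target`, `interaction`.
#' @slot genes node set.
#' @export
setClass("DirectedGRN",
    representation(edges = "data.frame", genes = "character"))

setValidity("DirectedGRN", function(object) {
    e <- object@edges
    msg <- character()
    if (nrow(e)) {
        if (any(e$regulator == e$target)) msg <- c(msg, "self-loop in GRN")
        if (anyDuplicated(paste(e$regulator, e$target)))
            msg <- c(msg, "duplicate directed edge")
    }
    if (length(msg)) msg else TRUE
})

#' Per-gene dysregulation scores over a directed GRN
#'
#' Holds, for one dataset, the per-edge regulation-strength summary
#' (state-averaged log expression ratios and their difference) and the
#' per-gene dysregulation score `d` with its across-gene Z standardisation.
#'
#' @slot geneTable data.frame: `gene`, `d`, `z`, `n_edges` (incident
#'   measurable edges).
#' @slot edgeTable data.frame: `regulator`, `target`, `r_bar_normal`,
#'   `r_bar_tumor`, `ds`, `p_value`, `significant`.
#' @slot datasetId dataset identifier.
#' @slot sigP per-edge significance threshold used.
#' @slot base log base of the regulation strength.
#' @export
setClass("DysregulationResult",
    representation(geneTable = "data.frame", edgeTable = "data.frame",
                   datasetId = "character", sigP = "numeric", base = "numeric"))

#' Cox risk-score stratification model
#'
#' Gene coefficients (multivariate Cox or user-fixed), per-sample risk scores
#' (the coefficient-weighted sum of expression), the median threshold and the
#' resulting high/low risk group per sample.
#'
#' @slot genes cluster gene symbols.
#' @slot beta named numeric coefficients.
#' @slot scores named numeric per-sample risk scores.
#' @slot threshold median risk score.
#' @slot groups named character, `"high"` or `"low"` per sample.
#' @export
setClass("RiskModel",
    representation(genes = "character", beta = "numeric", scores = "numeric",
                   threshold = "numeric", groups = "character"))

setValidity("RiskModel", function(object) {
    if (!all(object@groups %in% c("high", "low")))
        return("groups must be 'high' or 'low'")
    TRUE
})
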