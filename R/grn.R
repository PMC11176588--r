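#' Construct a DirectedGRN
#'
#' @param edges data.frame with columns `regulator`, `target` and optionally
#'   `interaction`. Self-loops are removed and duplicate directed edges
#'   collapsed.
#' @param excludePredicted drop edges whose interaction label contains
#'   "predicted" (case-insensitive); default TRUE.
#' @return A [DirectedGRN-class].
#' @export
DirectedGRN <- function(edges, excludePredicted = TRUE) {
    e <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(e)[1:2] <- c("regulator", "target")
    if (!"interaction" %in% names(e)) e$interaction <- ""
    e$regulator <- toupper(as.character(e$regulator))
    e$target <- toupper(as.character(e$target))
    if (excludePredicted)
        e <- e[!grepl("predicted", e$interaction, ignore.case = TRUE), , drop = FALSE]
    e <- e[e$regulator != e$target, , drop = FALSE]
    e <- e[!duplicated(paste(e$regulator, e$target)), , drop = FALSE]
    rownames(e) <- NULL
    methods::new("DirectedGRN", edges = e[, c("regulator", "target", "interaction")],
                 genes = sort(unique(c(e$regulator, e$target))))
}

#' Read a directed GRN from a TSV edge list
#'
#' @param path TSV with columns regulator, target and optionally an
#'   interaction label.
#' @param excludePredicted see [DirectedGRN()].
#' @return A [DirectedGRN-class].
#' @export
readGRN <- function(path, excludePredicted = TRUE) {
    DirectedGRN(read.delim(path, stringsAsFactors = FALSE),
                excludePredicted = excludePredicted)
}

#' Regulation strength of a gene pair
#'
#' The log ratio of the (linear-scale) expression of a regulator to its
#' interacting gene, `log_base(e_i / e_j)`.
#'
#' @param eI,eJ positive linear-scale expression values (vectorised).
#' @param base log base, 2 (default) or `exp(1)`.
#' @return Numeric regulation strength.
#' @examples
#' regulationStrength(8, 2)   # 2
#' @export
regulationStrength <- function(eI, eJ, base = 2) {
    if (any(eI <= 0) || any(eJ <= 0))
        stopf("expression values must be positive on the linear scale")
    log(eI / eJ, base = base)
}

#' Per-edge dysregulation strength between states
#'
#' For one directed GRN edge, computes the per-sample regulation strength
#' `r_ij = log_base(E_i / E_j)` in each state, averages within state, and
#' returns the dysregulation strength `ds = mean(tumor) - mean(normal)` with
#' a two-sided Welch t-test p-value comparing the per-sample values between
#' states. Stored log2 matrices are exponentiated before forming the ratio.
#'
#' @param ds a [StateExpression-class] (log2 values).
#' @param regulator,target gene symbols present in the dataset.
#' @param base log base of the regulation strength (default 2).
#' @return list with `r_bar_normal`, `r_bar_tumor`, `ds`, `p_value`.
#' @export
edgeDysregulation <- function(ds, regulator, target, base = 2) {
    if (!all(c(regulator, target) %in% rownames(ds)))
        stopf("gene '%s' or '%s' missing from dataset", regulator, target)
    st <- stateLabels(ds)
    if (sum(st == "normal") < 2 || sum(st == "tumor") < 2)
        stopf(">=2 samples per state are required")
    m <- exprValues(ds)
    # log2 storage: r per sample = (x_i - x_j) * log(2)/log(base)
    r <- (m[regulator, ] - m[target, ]) * log(2, base = base)
    w <- welchVec(r[st == "tumor"], r[st == "normal"])
    list(r_bar_normal = mean(r[st == "normal"]),
         r_bar_tumor = mean(r[st == "tumor"]),
         ds = w$estimate, p_value = w$p)
}

#' Per-gene dysregulation scores over a directed GRN
#'
#' For every GRN edge measurable in the dataset, the dysregulation strength
#' and its Welch p-value are computed ([edgeDysregulation()]). The
#' dysregulation score of gene i sums the absolute dysregulation strengths of
#' all its incident edges (upstream and downstream) that are significant at
#' `sigP`; genes with no significant incident edge score 0. Z-scores
#' standardise the scores over all genes with at least one measurable
#' incident edge.
#'
#' @param grn a [DirectedGRN-class].
#' @param ds a [StateExpression-class].
#' @param sigP per-edge significance threshold (default 0.05).
#' @param base log base (default 2); Z-scores are invariant to it.
#' @param absolute sum `|ds|` (default TRUE) or signed `ds`.
#' @return A [DysregulationResult-class].
#' @export
geneDysregulationScores <- function(grn, ds, sigP = 0.05, base = 2,
                                    absolute = TRUE) {
    e <- grn@edges
    measurable <- e$regulator %in% rownames(ds) & e$target %in% rownames(ds)
    if (any(!measurable))
        message(sprintf("skipping %d GRN edges with genes missing from '%s'",
                        sum(!measurable), datasetId(ds)))
    e <- e[measurable, , drop = FALSE]
    st <- stateLabels(ds)
    m <- exprValues(ds)
    scale <- log(2, base = base)
    rmat <- (m[e$regulator, , drop = FALSE] - m[e$target, , drop = FALSE]) * scale
    w <- welchRows(rmat[, st == "tumor", drop = FALSE],
                   rmat[, st == "normal", drop = FALSE])
    edgeTab <- data.frame(
        regulator = e$regulator, target = e$target,
        r_bar_normal = rowMeans(rmat[, st == "normal", drop = FALSE]),
        r_bar_tumor = rowMeans(rmat[, st == "tumor", drop = FALSE]),
        ds = unname(w$estimate), p_value = unname(w$p),
        significant = unname(w$p) < sigP, stringsAsFactors = FALSE)
    rownames(edgeTab) <- NULL
    scored <- sort(unique(c(e$regulator, e$target)))
    if (length(scored) < 3)
        stopf("fewer than 3 genes with measurable GRN edges; Z undefined")
    contrib <- if (absolute) abs(edgeTab$ds) else edgeTab$ds
    contrib[!edgeTab$significant] <- 0
    d <- vapply(scored, function(g)
        sum(contrib[edgeTab$regulator == g | edgeTab$target == g]), 0)
    nEdges <- vapply(scored, function(g)
        sum(edgeTab$regulator == g | edgeTab$target == g), 0L)
    sdd <- sd(d)
    # all scores equal (e.g. no significant edge anywhere): no gene deviates
    z <- if (sdd > 0) (d - mean(d)) / sdd else rep(0, length(d))
    geneTab <- data.frame(gene = scored, d = unname(d), z = unname(z),
                          n_edges = unname(nEdges), stringsAsFactors = FALSE)
    rownames(geneTab) <- NULL
    methods::new("DysregulationResult", geneTable = geneTab,
                 edgeTable = edgeTab, datasetId = datasetId(ds),
                 sigP = sigP, base = base)
}

#' Genes highly dysregulated in every dataset
#'
#' @param results list of [DysregulationResult-class], one per dataset.
#' @param zMin Z-score threshold (default 5, inclusive).
#' @return Sorted character vector of genes with `z >= zMin` in every
#'   dataset.
#' @export
intersectHighZ <- function(results, zMin = 5) {
    if (!length(results)) stopf("at least one result is required")
    high <- lapply(results, function(r) r@geneTable$gene[r@geneTable$z >= zMin])
    sort(Reduce(intersect, high))
}
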