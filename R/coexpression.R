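#' Pearson correlation with t-distributed p-value
#'
#' Sample Pearson correlation with the two-sided p-value of
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. A
#' perfect correlation (|r| = 1) returns p = 0.
#'
#' @param x,y numeric vectors of equal length (n >= 3) with nonzero variance.
#' @return list with elements `r` and `p`.
#' @examples
#' pearsonTest(1:5, c(2, 4, 5, 4, 5))
#' @export
pearsonTest <- function(x, y) {
    n <- length(x)
    if (length(y) != n) stopf("x and y must have equal length")
    if (n < 3) stopf("at least 3 observations are required")
    dx <- x - mean(x)
    dy <- y - mean(y)
    sx <- sqrt(sum(dx^2))
    sy <- sqrt(sum(dy^2))
    if (sx == 0 || sy == 0) stopf("zero variance input")
    r <- sum(dx * dy) / (sx * sy)
    r <- min(1, max(-1, r))
    if (abs(r) >= 1 - 1e-15) return(list(r = r, p = 0))
    t <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * pt(abs(t), n - 2, lower.tail = FALSE))
}

#' State-specific co-expression network of one dataset
#'
#' All unordered gene pairs whose within-state Pearson correlation satisfies
#' `|r| >= rMin` and `p < pMax`. Genes with zero variance in the chosen state
#' are excluded from pairing with a warning.
#'
#' @param ds a [StateExpression-class].
#' @param state `"normal"` or `"tumor"` (>= 3 samples required).
#' @param rMin minimum absolute correlation (default 0.7).
#' @param pMax p-value threshold (default 0.05).
#' @return A [CoexpressionNetwork-class].
#' @export
stateNetwork <- function(ds, state, rMin = 0.7, pMax = 0.05) {
    m <- exprValues(ds, state)
    n <- ncol(m)
    if (n < 3) stopf("state '%s' has %d samples; >=3 required", state, n)
    v <- apply(m, 1, stats::var)
    if (any(v == 0)) {
        warnf("dropping %d zero-variance genes in state '%s'", sum(v == 0), state)
        m <- m[v > 0, , drop = FALSE]
    }
    C <- cor(t(m))
    keepIdx <- which(upper.tri(C) & abs(C) >= rMin, arr.ind = TRUE)
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        r = numeric(), p_value = numeric(),
                        stringsAsFactors = FALSE)
    if (nrow(keepIdx)) {
        r <- C[keepIdx]
        p <- ifelse(abs(r) >= 1 - 1e-15, 0,
                    2 * pt(abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2,
                           lower.tail = FALSE))
        ok <- p < pMax
        g <- rownames(m)
        edges <- data.frame(gene_a = g[keepIdx[ok, 1]],
                            gene_b = g[keepIdx[ok, 2]],
                            r = r[ok], p_value = p[ok],
                            stringsAsFactors = FALSE)
        edges <- canonicalizePairs(edges)
        edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
        rownames(edges) <- NULL
    }
    methods::new("CoexpressionNetwork", edges = edges, state = state,
                 datasetIds = datasetId(ds), rMin = rMin, pMax = pMax)
}

#' Sign-consistent consensus co-expression network
#'
#' Keeps the gene pairs present in every input network with the same sign of
#' correlation throughout. The consensus `r` is the arithmetic mean over
#' datasets; the stored p-value is the maximum (most conservative) across
#' datasets.
#'
#' @param nets list of [CoexpressionNetwork-class] objects for one state, one
#'   per dataset.
#' @return A [CoexpressionNetwork-class] whose `datasetIds` lists all inputs.
#' @export
consensusNetwork <- function(nets) {
    if (!length(nets)) stopf("at least one network is required")
    states <- unique(vapply(nets, function(x) x@state, ""))
    if (length(states) != 1) stopf("mixed states in consensus input: %s",
                                   paste(states, collapse = ", "))
    keys <- lapply(nets, function(x) pairKey(x@edges$gene_a, x@edges$gene_b))
    common <- Reduce(intersect, keys)
    first <- nets[[1]]@edges
    idx <- match(common, keys[[1]])
    out <- first[idx, , drop = FALSE]
    if (length(common)) {
        rmat <- sapply(nets, function(x)
            x@edges$r[match(common, pairKey(x@edges$gene_a, x@edges$gene_b))])
        pmat <- sapply(nets, function(x)
            x@edges$p_value[match(common, pairKey(x@edges$gene_a, x@edges$gene_b))])
        rmat <- matrix(rmat, nrow = length(common))
        pmat <- matrix(pmat, nrow = length(common))
        consistent <- apply(rmat > 0, 1, all) | apply(rmat < 0, 1, all)
        out <- out[consistent, , drop = FALSE]
        out$r <- rowMeans(rmat)[consistent]
        out$p_value <- apply(pmat, 1, max)[consistent]
        out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
        rownames(out) <- NULL
    }
    methods::new("CoexpressionNetwork", edges = out, state = states,
                 datasetIds = unlist(lapply(nets, function(x) x@datasetIds)),
                 rMin = nets[[1]]@rMin, pMax = nets[[1]]@pMax)
}

#' Write a co-expression network as an edge-list TSV or SIF file
#'
#' @param net a [CoexpressionNetwork-class].
#' @param path output file.
#' @param format `"tsv"` (gene_a, gene_b, r, p_value, state) or `"sif"`
#'   (gene_a, interaction tag `coexp`, gene_b).
#' @return Invisibly, the path written.
#' @export
writeNetwork <- function(net, path, format = c("tsv", "sif")) {
    format <- match.arg(format)
    e <- net@edges
    if (format == "tsv") {
        e$state <- rep(net@state, nrow(e))
        write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        write.table(data.frame(e$gene_a, "coexp", e$gene_b), path, sep = "\t",
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}
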