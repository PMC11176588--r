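# Independent oracles and toy builders shared across tests. These are
# deliberately naive (literal enumeration / closed forms) and share no code
# with the package internals they check.

# Literal evaluation of the two pathway cross-talk criteria on an edge list.
bruteCrosstalk <- function(A, B, edges) {
    hasEdge <- function(x, y)
        any((edges$gene_a == x & edges$gene_b == y) |
            (edges$gene_a == y & edges$gene_b == x))
    exA <- setdiff(A, B)
    exB <- setdiff(B, A)
    shared <- intersect(A, B)
    bridges <- 0L
    for (gi in exA) for (gj in exB) if (hasEdge(gi, gj)) bridges <- bridges + 1L
    critI <- bridges >= 2L
    critII <- FALSE
    for (gl in shared) {
        toA <- any(vapply(exA, function(gk) hasEdge(gk, gl), TRUE))
        toB <- any(vapply(exB, function(gm) hasEdge(gl, gm), TRUE))
        if (toA && toB) { critII <- TRUE; break }
    }
    list(crosstalk = critI || critII, critI = critI, critII = critII)
}

# Betweenness by exhaustive simple-path enumeration (feasible for <= 8 nodes):
# for every unordered pair, enumerate all simple paths, keep the shortest,
# and credit each interior node with its fraction of shortest paths.
bruteBetweenness <- function(edges) {
    nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
    adj <- lapply(nodes, function(v) unique(c(
        edges$gene_b[edges$gene_a == v], edges$gene_a[edges$gene_b == v])))
    names(adj) <- nodes
    score <- setNames(rep(0, length(nodes)), nodes)
    paths <- function(from, to, visited) {
        if (from == to) return(list(visited))
        out <- list()
        for (nb in setdiff(adj[[from]], visited))
            out <- c(out, paths(nb, to, c(visited, nb)))
        out
    }
    for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
        if (i >= j) next
        ps <- paths(nodes[i], nodes[j], nodes[i])
        if (!length(ps)) next
        lens <- vapply(ps, length, 1L)
        sp <- ps[lens == min(lens)]
        for (p in sp) for (v in p[-c(1, length(p))])
            score[v] <- score[v] + 1 / length(sp)
    }
    score
}

# Exact hypergeometric upper tail by direct summation of binomial ratios.
bruteHyper <- function(k, K, N, n) {
    i <- seq(k, min(K, n))
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Small StateExpression from a matrix with equal normal/tumor halves.
toySE <- function(m, id = "toy") {
    n <- ncol(m) / 2
    if (is.null(rownames(m))) rownames(m) <- sprintf("G%02d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
    StateExpression(m, rep(c("normal", "tumor"), each = n), id)
}

# CoexpressionNetwork directly from an edge list (bypasses thresholds).
toyNet <- function(gene_a, gene_b, r = 0.9, p = 0.001, state = "tumor",
                   dataset = "toy") {
    e <- data.frame(gene_a = pmin(gene_a, gene_b),
                    gene_b = pmax(gene_a, gene_b),
                    r = rep_len(r, length(gene_a)),
                    p_value = rep_len(p, length(gene_a)),
                    stringsAsFactors = FALSE)
    e <- e[!duplicated(paste(e$gene_a, e$gene_b)), , drop = FALSE]
    new("CoexpressionNetwork", edges = e, state = state, datasetIds = dataset,
        rMin = 0.7, pMax = 0.05)
}

# Random undirected edge list over n nodes, edge probability p.
randomEdges <- function(n, p = 0.4) {
    nodes <- sprintf("N%d", seq_len(n))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < p
    data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
               stringsAsFactors = FALSE)
}
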