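#' Exact set difference of two edge sets
#'
#' Partitions the union of two undirected edge sets (pathway-level or
#' gene-level; the first two columns of each data.frame are the node pair)
#' into edges only in the first network, edges only in the second, and
#' conserved edges.
#'
#' @param netA,netB data.frames whose first two columns identify the
#'   unordered edge, or [CoexpressionNetwork-class]/[CrosstalkNetwork-class]
#'   objects (their edge tables are used).
#' @return list with data.frames `only_in_a`, `only_in_b`, `conserved` and a
#'   data.frame `nodes` summarising node counts per part.
#' @export
networkDifference <- function(netA, netB) {
    ea <- canonicalizePairs(asEdgeDf(netA))
    eb <- canonicalizePairs(asEdgeDf(netB))
    ka <- pairKey(ea[[1]], ea[[2]])
    kb <- pairKey(eb[[1]], eb[[2]])
    onlyA <- ea[!ka %in% kb, , drop = FALSE]
    onlyB <- eb[!kb %in% ka, , drop = FALSE]
    cons <- ea[ka %in% kb, , drop = FALSE]
    rownames(onlyA) <- rownames(onlyB) <- rownames(cons) <- NULL
    nodeCount <- function(e) length(unique(c(e[[1]], e[[2]])))
    list(only_in_a = onlyA, only_in_b = onlyB, conserved = cons,
         nodes = data.frame(part = c("only_in_a", "only_in_b", "conserved"),
                            n_edges = c(nrow(onlyA), nrow(onlyB), nrow(cons)),
                            n_nodes = c(nodeCount(onlyA), nodeCount(onlyB),
                                        nodeCount(cons))))
}

asEdgeDf <- function(x) {
    if (methods::is(x, "CoexpressionNetwork") || methods::is(x, "CrosstalkNetwork"))
        x@edges
    else as.data.frame(x, stringsAsFactors = FALSE)
}

asIgraph <- function(net) {
    e <- asEdgeDf(net)
    igraph::graph_from_data_frame(e[, 1:2], directed = FALSE)
}

#' Betweenness centrality of every node
#'
#' Unnormalised shortest-path betweenness with unit edge weights and
#' unordered-pair counting (Brandes' algorithm, via igraph); disconnected
#' graphs are handled per component.
#'
#' @param net an edge data.frame (first two columns are the node pair) or a
#'   network object.
#' @return Named numeric vector of betweenness scores.
#' @export
betweennessCentrality <- function(net) {
    g <- asIgraph(net)
    igraph::betweenness(g, directed = FALSE, weights = NA)
}

#' Connected components, largest first
#'
#' @param net an edge data.frame or network object.
#' @return list of character vectors of node names, ordered by decreasing
#'   size with ties broken by the lexicographically smallest member; each
#'   component's members are sorted.
#' @export
connectedComponents <- function(net) {
    e <- asEdgeDf(net)
    if (!nrow(e)) return(list())
    g <- asIgraph(net)
    comp <- igraph::components(g)
    parts <- split(names(comp$membership), comp$membership)
    parts <- lapply(parts, sort)
    ord <- order(-vapply(parts, length, 1L), vapply(parts, `[`, "", 1L))
    unname(parts[ord])
}

#' Key genes of a component by betweenness centrality
#'
#' Ranks the genes of one connected component by unnormalised betweenness in
#' the component's induced subgraph and returns the top `k`. Ties are broken
#' lexicographically; a tie crossing the rank-k boundary is reported with a
#' message.
#'
#' @param net an edge data.frame or network object.
#' @param component character vector of component members (subset of the
#'   network's nodes), e.g. one element of [connectedComponents()].
#' @param k number of key genes (default 10). When `k` exceeds the component
#'   size the full ranking is returned with a warning.
#' @return data.frame with columns `gene`, `betweenness`, `rank`.
#' @export
keyGenes <- function(net, component, k = 10) {
    e <- asEdgeDf(net)
    keep <- e[[1]] %in% component & e[[2]] %in% component
    sub <- e[keep, , drop = FALSE]
    b <- rep(0, length(component))
    names(b) <- component
    if (nrow(sub)) {
        bs <- betweennessCentrality(sub)
        b[names(bs)] <- bs
    }
    ord <- order(-b, names(b))
    b <- b[ord]
    if (k > length(b)) {
        warnf("k = %d exceeds component size %d; returning all", k, length(b))
        k <- length(b)
    } else if (k < length(b) && b[k] == b[k + 1]) {
        message(sprintf("tie at rank %d (score %g) broken lexicographically", k, b[k]))
    }
    data.frame(gene = names(b)[seq_len(k)], betweenness = unname(b[seq_len(k)]),
               rank = seq_len(k), stringsAsFactors = FALSE)
}
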