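#' Classify a gene relative to a pathway pair
#'
#' @param g gene symbol.
#' @param A,B character gene sets of the two pathways.
#' @return `"exclusive_A"`, `"exclusive_B"`, `"shared"` or `"neither"`.
#' @examples
#' classifyGene("X", A = c("X", "S"), B = c("Y", "S"))
#' @export
classifyGene <- function(g, A, B) {
    inA <- g %in% A
    inB <- g %in% B
    if (inA && inB) "shared"
    else if (inA) "exclusive_A"
    else if (inB) "exclusive_B"
    else "neither"
}

# Vectorised role classification used internally.
classifyGenes <- function(g, A, B) {
    inA <- g %in% A
    inB <- g %in% B
    out <- rep("neither", length(g))
    out[inA & !inB] <- "exclusive_A"
    out[!inA & inB] <- "exclusive_B"
    out[inA & inB] <- "shared"
    out
}

#' Detect cross-talk between two pathways from co-expressed gene pairs
#'
#' Two pathways are in cross-talk when the co-expression network satisfies at
#' least one of two criteria designed to exclude single-pair false positives:
#'
#' * criterion (i), `bridge_pair`: at least two distinct unordered
#'   co-expressed pairs, each joining a gene exclusive to pathway A to a gene
#'   exclusive to pathway B (the same gene may appear in both pairs);
#' * criterion (ii), `shared_gene`: a gene shared by both pathways that is
#'   co-expressed with at least one gene exclusive to A and at least one gene
#'   exclusive to B.
#'
#' The detection is symmetric in A and B.
#'
#' @param A,B character gene sets of the two pathways.
#' @param net a [CoexpressionNetwork-class] (typically the consensus network
#'   of one state).
#' @return `NULL` when no criterion holds, otherwise a list with `criterion`
#'   (`"bridge_pair"`, `"shared_gene"` or `"both"`) and `pairs`, a data.frame
#'   of the supporting co-expressed pairs with the role of each endpoint.
#' @export
detectCrosstalk <- function(A, B, net) {
    e <- net@edges
    if (!nrow(e)) return(NULL)
    ra <- classifyGenes(e$gene_a, A, B)
    rb <- classifyGenes(e$gene_b, A, B)
    touching <- ra != "neither" & rb != "neither"
    e <- e[touching, , drop = FALSE]
    ra <- ra[touching]
    rb <- rb[touching]
    bridge <- (ra == "exclusive_A" & rb == "exclusive_B") |
              (ra == "exclusive_B" & rb == "exclusive_A")
    critI <- sum(bridge) >= 2

    # criterion (ii): shared gene with edges into both exclusive sides
    sharedA <- c(e$gene_a[ra == "shared" & rb == "exclusive_A"],
                 e$gene_b[rb == "shared" & ra == "exclusive_A"])
    sharedB <- c(e$gene_a[ra == "shared" & rb == "exclusive_B"],
                 e$gene_b[rb == "shared" & ra == "exclusive_B"])
    linkers <- intersect(sharedA, sharedB)
    critII <- length(linkers) > 0

    if (!critI && !critII) return(NULL)
    chain <- (ra == "shared" & e$gene_a %in% linkers & rb != "shared" & rb != "neither") |
             (rb == "shared" & e$gene_b %in% linkers & ra != "shared" & ra != "neither")
    support <- if (critI && critII) bridge | chain else if (critI) bridge else chain
    pairs <- e[support, , drop = FALSE]
    pairs$role_a <- ra[support]
    pairs$role_b <- rb[support]
    rownames(pairs) <- NULL
    list(criterion = if (critI && critII) "both"
                     else if (critI) "bridge_pair" else "shared_gene",
         pairs = pairs)
}

#' Build the pathway cross-talk network and its interface gene network
#'
#' Evaluates [detectCrosstalk()] over every unordered pair of pathways in the
#' collection. The interface gene co-expression network (PathGeNet) is the
#' union of all supporting gene pairs over all cross-talk edges. Isolated
#' pathways are excluded from the node set.
#'
#' @param pc a (filtered) [PathwayCollection-class].
#' @param net a [CoexpressionNetwork-class] for one state.
#' @return A [CrosstalkNetwork-class]; `edgeTable()` gives the pathway pairs,
#'   `pathGeNet()` the interface gene network.
#' @export
buildCrosstalkNetwork <- function(pc, net) {
    ids <- sort(names(pc@sets))
    rows <- list()
    evidence <- list()
    geneEdges <- list()
    if (length(ids) >= 2) {
        for (i in seq_len(length(ids) - 1)) {
            for (j in seq(i + 1, length(ids))) {
                a <- ids[i]; b <- ids[j]
                ev <- detectCrosstalk(pc@sets[[a]], pc@sets[[b]], net)
                if (is.null(ev)) next
                key <- paste(a, b, sep = "|")
                rows[[key]] <- data.frame(
                    pathway_a = a, pathway_b = b, criterion = ev$criterion,
                    n_support_pairs = nrow(ev$pairs), stringsAsFactors = FALSE)
                evidence[[key]] <- ev$pairs
                geneEdges[[key]] <- ev$pairs[, c("gene_a", "gene_b", "r", "p_value")]
            }
        }
    }
    edges <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
             else data.frame(pathway_a = character(), pathway_b = character(),
                             criterion = character(),
                             n_support_pairs = integer(),
                             stringsAsFactors = FALSE)
    pg <- if (length(geneEdges)) {
        g <- do.call(rbind, c(geneEdges, make.row.names = FALSE))
        g <- g[!duplicated(pairKey(g$gene_a, g$gene_b)), , drop = FALSE]
        g <- g[order(g$gene_a, g$gene_b), , drop = FALSE]
        rownames(g) <- NULL
        g
    } else data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
    methods::new("CrosstalkNetwork", edges = edges, evidence = evidence,
                 pathGeNet = pg,
                 nodes = sort(unique(c(edges$pathway_a, edges$pathway_b))),
                 state = net@state)
}
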