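#' Hypergeometric pathway enrichment
#'
#' One-sided hypergeometric tail probability of observing at least the seen
#' overlap between a gene set of interest and each pathway, within a fixed
#' gene universe, with Benjamini-Hochberg adjustment.
#'
#' @param genes character vector of genes of interest (subset of
#'   `universe`).
#' @param pc a [PathwayCollection-class].
#' @param universe background gene set.
#' @return data.frame sorted by p-value: `pathway`, `overlap`,
#'   `pathway_size`, `p_value`, `p_adjust`, `genes` (comma-separated
#'   overlap).
#' @export
pathwayEnrichment <- function(genes, pc, universe) {
    genes <- toupper(genes)
    universe <- unique(toupper(universe))
    if (!length(genes)) stopf("empty gene set")
    if (!all(genes %in% universe)) stopf("genes must be a subset of the universe")
    N <- length(universe)
    n <- length(unique(genes))
    rows <- lapply(names(pc@sets), function(id) {
        K <- length(intersect(pc@sets[[id]], universe))
        ov <- intersect(pc@sets[[id]], genes)
        k <- length(ov)
        p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(pathway = id, overlap = k, pathway_size = K, p_value = p,
                   genes = paste(sort(ov), collapse = ","),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adjust <- p.adjust(out$p_value, method = "BH")
    out <- out[order(out$p_value, out$pathway),
               c("pathway", "overlap", "pathway_size", "p_value", "p_adjust",
                 "genes")]
    rownames(out) <- NULL
    out
}

#' Run the full discovery analysis
#'
#' Orchestrates the pipeline end to end: gene intersection across datasets,
#' differential expression, per-dataset/per-state co-expression networks,
#' sign-consistent consensus per state, pathway filtering, cross-talk
#' detection with PathGeNet extraction, normal-versus-tumor comparison,
#' connected components and betweenness key genes, GRN dysregulation scoring
#' with the cross-dataset high-Z intersection (when a GRN is supplied), risk
#' stratification of a gene cluster (when survival data are supplied) and
#' hypergeometric enrichment of the key genes. Every stage is recorded in a
#' manifest with the counts surviving it.
#'
#' @param config list (see [runConfigDefaults()]) with entries:
#'   `datasets` (list of [StateExpression-class], or `exprFiles` +
#'   `stateFiles` paths), `pathways` (a [PathwayCollection-class] or `gmt`
#'   path), optional `grn` ([DirectedGRN-class] or path), optional `survival`
#'   (list `expr` matrix and `surv` data.frame, or paths), optional
#'   `clusterGenes`, optional `excludedCategories`, optional `outDir`, and
#'   the thresholds of [runConfigDefaults()].
#' @return Invisibly, a list with `manifest` (stage log, thresholds, counts)
#'   and `results` (every intermediate object).
#' @export
runDiscovery <- function(config) {
    cfg <- utils::modifyList(runConfigDefaults(), config)
    stages <- list()
    note <- function(stage, status, ...) {
        stages[[stage]] <<- c(list(status = status), list(...))
    }

    datasets <- cfg$datasets
    if (is.null(datasets)) {
        if (is.null(cfg$exprFiles)) stopf("stage read: no datasets supplied")
        datasets <- mapply(function(e, s)
            readExpression(e, read.delim(s, stringsAsFactors = FALSE)),
            cfg$exprFiles, cfg$stateFiles, SIMPLIFY = FALSE)
    }
    note("read", "complete", n_datasets = length(datasets))

    datasets <- intersectGenes(datasets)
    universe <- rownames(datasets[[1]])
    note("intersect", "complete", n_common_genes = length(universe))

    de <- lapply(datasets, differentialExpression)
    names(de) <- vapply(datasets, datasetId, "")
    sig <- signatureGenes(de, lfcMin = cfg$lfcMin, pMax = cfg$deP,
                          genePool = universe)
    note("differential_expression", "complete",
         n_signature_up = length(sig$up), n_signature_down = length(sig$down))

    states <- c("normal", "tumor")
    perState <- lapply(states, function(st)
        lapply(datasets, stateNetwork, state = st, rMin = cfg$rMin,
               pMax = cfg$pMax))
    names(perState) <- states
    consensus <- lapply(perState, consensusNetwork)
    note("coexpression", "complete",
         n_consensus_edges_normal = nrow(edgeTable(consensus$normal)),
         n_consensus_edges_tumor = nrow(edgeTable(consensus$tumor)))

    pc <- cfg$pathways
    if (is.null(pc)) {
        if (is.null(cfg$gmt)) stopf("stage pathways: no pathway collection supplied")
        pc <- readGMT(cfg$gmt)
    }
    pcF <- filterPathways(pc, universe, minGenes = cfg$minGenes,
                          excludedCategories = cfg$excludedCategories)
    note("pathway_filter", "complete", n_pathways = length(geneSets(pcF)))

    xt <- lapply(consensus, function(net) buildCrosstalkNetwork(pcF, net))
    note("crosstalk", "complete",
         n_crosstalk_normal = nrow(edgeTable(xt$normal)),
         n_crosstalk_tumor = nrow(edgeTable(xt$tumor)),
         pathgenet_edges_tumor = nrow(pathGeNet(xt$tumor)))

    deltaPathway <- networkDifference(xt$normal, xt$tumor)
    deltaGene <- networkDifference(pathGeNet(xt$normal), pathGeNet(xt$tumor))
    note("compare", "complete",
         pathway_only_tumor = nrow(deltaPathway$only_in_b),
         pathway_conserved = nrow(deltaPathway$conserved),
         gene_only_tumor = nrow(deltaGene$only_in_b),
         gene_conserved = nrow(deltaGene$conserved))

    comps <- connectedComponents(pathGeNet(xt$tumor))
    keys <- if (length(comps))
        lapply(comps[seq_len(min(2, length(comps)))], function(cmp)
            keyGenes(pathGeNet(xt$tumor), cmp, k = min(cfg$k, length(cmp))))
    else list()
    note("key_genes", "complete", n_components = length(comps),
         n_key_genes = sum(vapply(keys, nrow, 0L)))

    dysreg <- NULL
    highZ <- character()
    grn <- cfg$grn
    if (is.character(grn)) grn <- readGRN(grn)
    if (!is.null(grn)) {
        dysreg <- lapply(datasets, function(d)
            geneDysregulationScores(grn, d, sigP = cfg$sigP))
        highZ <- intersectHighZ(dysreg, zMin = cfg$zMin)
        note("dysregulation", "complete", n_high_z = length(highZ))
    } else note("dysregulation", "skipped")

    survivalRes <- NULL
    if (!is.null(cfg$survival)) {
        sv <- cfg$survival
        if (is.character(sv$expr)) {
            m <- read.delim(sv$expr, check.names = FALSE)
            rn <- as.character(m[[1]])
            m <- as.matrix(m[, -1, drop = FALSE])
            rownames(m) <- rn
            sv$expr <- m
        }
        if (is.character(sv$surv)) sv$surv <- readSurvival(sv$surv)
        clusterGenes <- cfg$clusterGenes
        if (is.null(clusterGenes)) clusterGenes <- rownames(sv$expr)
        survivalRes <- evaluateCluster(sv$expr, sv$surv, genes = clusterGenes)
        note("survival", "complete",
             logrank_chi2 = survivalRes$logrank$chi2,
             logrank_p = survivalRes$logrank$p)
    } else note("survival", "skipped")

    keyGeneSet <- unique(unlist(lapply(keys, `[[`, "gene")))
    enrich <- if (length(keyGeneSet))
        pathwayEnrichment(keyGeneSet, pcF, universe)
    else NULL
    note("enrichment", if (length(keyGeneSet)) "complete" else "skipped")

    manifest <- list(
        thresholds = cfg[c("rMin", "pMax", "deP", "lfcMin", "minGenes",
                           "zMin", "k", "sigP")],
        datasets = vapply(datasets, datasetId, ""),
        stages = stages)
    results <- list(datasets = datasets, de = de, signature = sig,
                    perState = perState, consensus = consensus,
                    pathways = pcF, crosstalk = xt,
                    deltaPathway = deltaPathway, deltaGene = deltaGene,
                    components = comps, keyGenes = keys,
                    dysregulation = dysreg, highZ = highZ,
                    survival = survivalRes, enrichment = enrich)
    if (!is.null(cfg$outDir)) writeRunOutputs(cfg$outDir, manifest, results)
    invisible(list(manifest = manifest, results = results))
}

#' Default thresholds of the discovery pipeline
#'
#' `rMin` 0.7 and `pMax` 0.05 (co-expression), `deP` 0.01 and `lfcMin` 0.5
#' (differential expression / signatures), `minGenes` 5 (pathway filter),
#' `zMin` 5 (dysregulation), `k` 10 (key genes), `sigP` 0.05 (per-edge
#' dysregulation significance).
#'
#' @return Named list of defaults, overridable entry-wise in the config
#'   passed to [runDiscovery()].
#' @export
runConfigDefaults <- function() {
    list(rMin = 0.7, pMax = 0.05, deP = 0.01, lfcMin = 0.5, minGenes = 5,
         zMin = 5, k = 10, sigP = 0.05,
         excludedCategories = character(),
         datasets = NULL, exprFiles = NULL, stateFiles = NULL,
         pathways = NULL, gmt = NULL, grn = NULL, survival = NULL,
         clusterGenes = NULL, outDir = NULL)
}

writeRunOutputs <- function(outDir, manifest, results) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (st in names(results$consensus))
        writeNetwork(results$consensus[[st]],
                     file.path(outDir, sprintf("consensus_%s.tsv", st)))
    for (st in names(results$crosstalk)) {
        write.table(edgeTable(results$crosstalk[[st]]),
                    file.path(outDir, sprintf("crosstalk_%s.tsv", st)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(pathGeNet(results$crosstalk[[st]]),
                    file.path(outDir, sprintf("pathgenet_%s.tsv", st)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        pg <- pathGeNet(results$crosstalk[[st]])
        write.table(data.frame(pg$gene_a, rep("coexp", nrow(pg)), pg$gene_b),
                    file.path(outDir, sprintf("pathgenet_%s.sif", st)),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    }
    if (length(results$keyGenes))
        write.table(do.call(rbind, lapply(seq_along(results$keyGenes),
            function(i) cbind(component = i, results$keyGenes[[i]]))),
            file.path(outDir, "key_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(results$dysregulation)) {
        for (r in results$dysregulation)
            write.table(geneScores(r),
                        file.path(outDir, sprintf("dysregulation_%s.tsv",
                                                  r@datasetId)),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(results$highZ, file.path(outDir, "high_z_genes.txt"))
    }
    if (!is.null(results$enrichment))
        write.table(results$enrichment, file.path(outDir, "enrichment.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(outDir)
}

#' Read a pipeline configuration from YAML
#'
#' Convenience wrapper turning a YAML file of paths and thresholds into the
#' config list consumed by [runDiscovery()].
#'
#' @param path YAML file.
#' @return list suitable for [runDiscovery()].
#' @export
readRunConfig <- function(path) {
    yaml::read_yaml(path)
}
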