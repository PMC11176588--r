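#' Configuration for the synthetic study generator
#'
#' Defines a seed-reproducible multi-dataset study with planted ground truth
#' for every pipeline stage: paired-state expression with sign-consistent
#' co-expression modules that exist only in the designated state, overlapping
#' pathway gene sets laid out in a chain, planted pathway cross-talks of both
#' evidence criteria, a directed GRN whose hub edges receive a log2
#' expression-ratio shift in tumor samples, and a survival cohort drawn from
#' an exponential proportional-hazards model on a planted gene cluster.
#'
#' @param nDatasets number of expression datasets (default 3).
#' @param nPerState samples per state per dataset; scalar or vector of
#'   length `nDatasets` (default 20).
#' @param nPathways,pathwaySize,chainOverlap pathway layout: `nPathways`
#'   sets of `pathwaySize` genes, consecutive pathways sharing
#'   `chainOverlap` genes (so every pathway has a >=2-gene partner and
#'   survives retention filtering). Defaults 6, 12, 2.
#' @param nBridgeModules bridging gene-pair modules planted between the first
#'   two pathways (criterion i evidence; default 3).
#' @param nSharedChains shared-gene chains planted between the third and
#'   fourth pathways (criterion ii evidence; default 2, at most
#'   `chainOverlap`).
#' @param rho within-module correlation in the active state (default 0.9).
#' @param moduleState state in which planted modules are correlated
#'   (`"tumor"`, `"normal"` or `"both"`; default `"tumor"`, i.e. the modules
#'   rewire between states).
#' @param nHubs,hubTargets,delta GRN layout: each hub regulates `hubTargets`
#'   genes whose tumor expression is shifted by `delta` log2 units (defaults
#'   2, 10, 1).
#' @param nNullGrnGenes,nNullGrnEdges unshifted background GRN (defaults 30
#'   genes, 40 random directed edges).
#' @param nNoiseGenes unstructured genes outside pathways and GRN (default 6).
#' @param noiseSd within-state log2 expression standard deviation (default
#'   0.5).
#' @param baselineMean,baselineSd per-gene baseline log2 means are drawn from
#'   N(baselineMean, baselineSd) per dataset (defaults 7, 1).
#' @param survN survival cohort size (default 100).
#' @param clusterBeta true Cox coefficients of the planted prognostic
#'   cluster; its length sets the cluster size (default
#'   `c(0.8, -0.6, 0.5, -0.4, 0.3)`).
#' @param baselineHazard exponential baseline hazard (default 0.1).
#' @param censorUpper upper bound of the independent uniform censoring time
#'   (default 30, about 30 percent censoring at these defaults).
#' @param seed integer seed fixing every draw.
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nDatasets = 3, nPerState = 20, nPathways = 6,
                            pathwaySize = 12, chainOverlap = 2,
                            nBridgeModules = 3, nSharedChains = 2,
                            rho = 0.9, moduleState = "tumor",
                            nHubs = 2, hubTargets = 10, delta = 1,
                            nNullGrnGenes = 30, nNullGrnEdges = 40,
                            nNoiseGenes = 6, noiseSd = 0.5,
                            baselineMean = 7, baselineSd = 1,
                            survN = 100,
                            clusterBeta = c(0.8, -0.6, 0.5, -0.4, 0.3),
                            baselineHazard = 0.1, censorUpper = 30,
                            seed = 1) {
    cfg <- as.list(environment())
    if (length(cfg$nPerState) == 1)
        cfg$nPerState <- rep(cfg$nPerState, nDatasets)
    if (length(cfg$nPerState) != nDatasets)
        stopf("nPerState must be scalar or length nDatasets")
    if (cfg$rho <= 0 || cfg$rho >= 1) stopf("rho must be in (0, 1)")
    if (nPathways < 4) stopf("at least 4 pathways are required for planting")
    if (chainOverlap >= pathwaySize)
        stopf("chainOverlap must be smaller than pathwaySize")
    if (nSharedChains > chainOverlap)
        stopf("nSharedChains cannot exceed chainOverlap (shared genes)")
    interior <- pathwaySize - 2 * chainOverlap
    if (nBridgeModules > interior || nSharedChains > interior)
        stopf("planting exceeds the exclusive interior of a pathway (%d genes)",
              interior)
    if (any(unlist(cfg[c("nDatasets", "nPathways", "pathwaySize", "nHubs",
                         "hubTargets", "survN")]) <= 0))
        stopf("counts must be positive")
    if (!moduleState %in% c("normal", "tumor", "both"))
        stopf("moduleState must be 'normal', 'tumor' or 'both'")
    class(cfg) <- "SyntheticConfig"
    cfg
}

# Deterministic layout (gene names, pathway sets, modules, GRN) shared by the
# planted and null generators. No randomness except the null-GRN edge sample.
studyLayout <- function(cfg) {
    stride <- cfg$pathwaySize - cfg$chainOverlap
    nPathGenes <- cfg$nPathways * cfg$pathwaySize -
        (cfg$nPathways - 1) * cfg$chainOverlap
    nGrnGenes <- cfg$nHubs * (1 + cfg$hubTargets) + cfg$nNullGrnGenes
    nGenes <- nPathGenes + nGrnGenes + cfg$nNoiseGenes
    genes <- sprintf("G%04d", seq_len(nGenes))

    pwIdx <- lapply(seq_len(cfg$nPathways), function(i)
        seq((i - 1) * stride + 1, (i - 1) * stride + cfg$pathwaySize))
    sets <- stats::setNames(lapply(pwIdx, function(ix) genes[ix]),
                            sprintf("PW%d", seq_len(cfg$nPathways)))

    # criterion (i): bridge modules between PW1-exclusive and PW2-interior genes
    p1 <- pwIdx[[1]]; p2 <- pwIdx[[2]]; p3 <- pwIdx[[3]]; p4 <- pwIdx[[4]]
    interior2 <- setdiff(p2, c(p1, p3))
    bridges <- lapply(seq_len(cfg$nBridgeModules), function(k)
        c(genes[p1[k]], genes[interior2[k]]))
    # criterion (ii): chains exclusive(PW3) - shared(PW3,PW4) - exclusive(PW4)
    shared34 <- intersect(p3, p4)
    interior3 <- setdiff(p3, c(p2, p4))
    p5 <- if (cfg$nPathways >= 5) pwIdx[[5]] else integer()
    interior4 <- setdiff(p4, c(p3, p5))
    chains <- lapply(seq_len(cfg$nSharedChains), function(k)
        c(genes[interior3[k]], genes[shared34[k]], genes[interior4[k]]))

    grnStart <- nPathGenes
    hubs <- genes[grnStart + seq_len(cfg$nHubs)]
    targets <- lapply(seq_len(cfg$nHubs), function(h)
        genes[grnStart + cfg$nHubs + (h - 1) * cfg$hubTargets +
              seq_len(cfg$hubTargets)])
    nullGenes <- genes[grnStart + cfg$nHubs * (1 + cfg$hubTargets) +
                       seq_len(cfg$nNullGrnGenes)]

    list(genes = genes, sets = sets, bridges = bridges, chains = chains,
         hubs = hubs, targets = targets, nullGenes = nullGenes,
         crosstalk = data.frame(
             pathway_a = c("PW1", "PW3"), pathway_b = c("PW2", "PW4"),
             criterion = c("bridge_pair", "shared_gene"),
             stringsAsFactors = FALSE))
}

generate <- function(cfg, planted) {
    set.seed(cfg$seed)
    lay <- studyLayout(cfg)

    # directed GRN: hub -> targets plus random background edges
    grnEdges <- do.call(rbind, lapply(seq_len(cfg$nHubs), function(h)
        data.frame(regulator = lay$hubs[h], target = lay$targets[[h]],
                   interaction = "regulation", stringsAsFactors = FALSE)))
    ng <- length(lay$nullGenes)
    pool <- expand.grid(regulator = lay$nullGenes, target = lay$nullGenes,
                        stringsAsFactors = FALSE)
    pool <- pool[pool$regulator != pool$target, ]
    bg <- pool[sample(nrow(pool), min(cfg$nNullGrnEdges, nrow(pool))), ]
    bg$interaction <- "regulation"
    grn <- DirectedGRN(rbind(grnEdges, bg))

    modules <- if (planted) c(lay$bridges, lay$chains) else list()
    shifted <- if (planted) unlist(lay$targets) else character()

    datasets <- lapply(seq_len(cfg$nDatasets), function(d) {
        n <- cfg$nPerState[d]
        mu <- rnorm(length(lay$genes), cfg$baselineMean, cfg$baselineSd)
        mkState <- function(state) {
            x <- mu + cfg$noiseSd *
                matrix(rnorm(length(lay$genes) * n), ncol = n)
            active <- cfg$moduleState %in% c(state, "both")
            if (active) {
                for (mod in modules) {
                    ix <- match(mod, lay$genes)
                    f <- rnorm(n)
                    x[ix, ] <- mu[ix] + cfg$noiseSd *
                        (sqrt(cfg$rho) * matrix(f, length(ix), n, byrow = TRUE) +
                         sqrt(1 - cfg$rho) *
                         matrix(rnorm(length(ix) * n), ncol = n))
                }
            }
            if (state == "tumor" && length(shifted))
                x[match(shifted, lay$genes), ] <-
                    x[match(shifted, lay$genes), ] + cfg$delta
            x
        }
        m <- cbind(mkState("normal"), mkState("tumor"))
        rownames(m) <- lay$genes
        colnames(m) <- c(sprintf("D%dN%02d", d, seq_len(n)),
                         sprintf("D%dT%02d", d, seq_len(n)))
        StateExpression(m, rep(c("normal", "tumor"), each = n),
                        sprintf("SIM%d", d))
    })

    clusterGenes <- sprintf("SG%d", seq_along(cfg$clusterBeta))
    sx <- matrix(rnorm(length(clusterGenes) * cfg$survN),
                 nrow = length(clusterGenes),
                 dimnames = list(clusterGenes,
                                 sprintf("P%03d", seq_len(cfg$survN))))
    eta <- if (planted) colSums(sx * cfg$clusterBeta) else rep(0, cfg$survN)
    tEvent <- rexp(cfg$survN, rate = cfg$baselineHazard * exp(eta))
    tCens <- runif(cfg$survN, 0, cfg$censorUpper)
    survTab <- data.frame(sample = colnames(sx),
                          time = pmin(tEvent, tCens),
                          event = as.integer(tEvent <= tCens),
                          stringsAsFactors = FALSE)

    truth <- list(
        crosstalk = if (planted) lay$crosstalk else lay$crosstalk[0, ],
        bridgePairs = if (planted) do.call(rbind, lapply(c(
            lapply(lay$bridges, function(m) m[c(1, 2)]),
            lapply(lay$chains, function(m) rbind(m[c(1, 2)], m[c(2, 3)]))),
            function(p) {
                p <- matrix(p, ncol = 2)
                data.frame(gene_a = pmin(p[, 1], p[, 2]),
                           gene_b = pmax(p[, 1], p[, 2]),
                           stringsAsFactors = FALSE)
            })) else data.frame(gene_a = character(), gene_b = character()),
        hubs = if (planted) lay$hubs else character(),
        hubTargets = if (planted) lay$targets else list(),
        clusterGenes = clusterGenes,
        clusterBeta = if (planted) stats::setNames(cfg$clusterBeta, clusterGenes)
                      else stats::setNames(rep(0, length(clusterGenes)),
                                           clusterGenes),
        modules = modules)

    list(datasets = datasets,
         pathways = PathwayCollection(lay$sets),
         grn = grn,
         survival = list(expr = sx, surv = survTab),
         truth = truth,
         config = cfg)
}

#' Generate a synthetic study with planted ground truth
#'
#' @param cfg a [syntheticConfig()].
#' @return list with elements `datasets` (list of
#'   [StateExpression-class]), `pathways` ([PathwayCollection-class]), `grn`
#'   ([DirectedGRN-class]), `survival` (list `expr`, `surv`), `truth` (the
#'   planted ground truth: cross-talk pairs, bridging gene pairs, hub genes,
#'   prognostic cluster and its coefficients) and `config`.
#' @examples
#' study <- generateStudy(syntheticConfig(seed = 7))
#' study$datasets[[1]]
#' @export
generateStudy <- function(cfg = syntheticConfig()) generate(cfg, planted = TRUE)

#' Generate a matched null study with all planting disabled
#'
#' Identical layout (pathways, GRN topology, cohort size) but independent
#' genes, no expression-ratio shift and survival independent of expression;
#' used for calibration.
#'
#' @param cfg a [syntheticConfig()].
#' @return Same structure as [generateStudy()], with empty planted truth.
#' @export
generateNullStudy <- function(cfg = syntheticConfig()) generate(cfg, planted = FALSE)

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits, under `dir`: one expression TSV and state-map TSV per dataset, the
#' pathway collection as GMT, the GRN edge TSV, the survival cohort
#' (expression TSV + survival TSV) and a machine-readable JSON manifest of
#' the planted ground truth.
#'
#' @param study result of [generateStudy()] or [generateNullStudy()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()
    for (ds in study$datasets) {
        id <- datasetId(ds)
        pe <- file.path(dir, paste0(id, "_expr.tsv"))
        ps <- file.path(dir, paste0(id, "_states.tsv"))
        m <- exprValues(ds)
        write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                    pe, sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(data.frame(sample = colnames(m), state = stateLabels(ds)),
                    ps, sep = "\t", quote = FALSE, row.names = FALSE)
        paths[[paste0(id, "_expr")]] <- pe
        paths[[paste0(id, "_states")]] <- ps
    }
    gmt <- file.path(dir, "pathways.gmt")
    writeLines(vapply(names(geneSets(study$pathways)), function(id)
        paste(c(id, "synthetic pathway", geneSets(study$pathways)[[id]]),
              collapse = "\t"), ""), gmt)
    paths$gmt <- gmt
    grnPath <- file.path(dir, "grn.tsv")
    write.table(edgeTable(study$grn), grnPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$grn <- grnPath
    se <- file.path(dir, "surv_expr.tsv")
    write.table(data.frame(gene = rownames(study$survival$expr),
                           study$survival$expr, check.names = FALSE),
                se, sep = "\t", quote = FALSE, row.names = FALSE)
    sv <- file.path(dir, "survival.tsv")
    write.table(study$survival$surv, sv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$surv_expr <- se
    paths$survival <- sv
    tr <- file.path(dir, "truth.json")
    jsonlite::write_json(study$truth, tr, auto_unbox = TRUE, digits = NA)
    paths$truth <- tr
    invisible(paths)
}
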