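test_that("regulationStrength is the log expression ratio", {
    expect_equal(regulationStrength(5, 5), 0)
    expect_equal(regulationStrength(4, 2), 1)
    expect_equal(regulationStrength(8, 2), 2)
    expect_equal(regulationStrength(8, 2, base = exp(1)), log(4))
    expect_error(regulationStrength(0, 2), "positive")
})

test_that("DirectedGRN construction cleans the edge list", {
    e <- data.frame(regulator = c("a", "a", "b", "c"),
                    target = c("b", "b", "b", "d"),
                    interaction = c("binding", "binding", "self", "predicted: x"))
    e$target[3] <- "b"  # self-loop
    grn <- DirectedGRN(e)
    expect_equal(nrow(edgeTable(grn)), 1L)  # dup collapsed, self-loop + predicted dropped
    expect_equal(edgeTable(grn)$regulator, "A")
    grn2 <- DirectedGRN(e, excludePredicted = FALSE)
    expect_equal(nrow(edgeTable(grn2)), 2L)
})

test_that("edgeDysregulation matches hand-computed state means", {
    # 4 normal + 4 tumor samples; log2 values chosen so per-sample ratios are exact
    m <- rbind(A = c(3, 4, 5, 6, 5, 6, 7, 8),
               B = c(1, 2, 3, 4, 2, 3, 4, 5))
    colnames(m) <- sprintf("S%d", 1:8)
    ds <- StateExpression(m, rep(c("normal", "tumor"), each = 4), "toy")
    r <- edgeDysregulation(ds, "A", "B")
    # per-sample r = A - B: normal all 2, tumor all 3
    expect_equal(r$r_bar_normal, 2, tolerance = 1e-12)
    expect_equal(r$r_bar_tumor, 3, tolerance = 1e-12)
    expect_equal(r$ds, 1, tolerance = 1e-12)

    # identical ratios in both states: ds = 0, p = 1
    m2 <- rbind(A = c(3, 4, 5, 6, 3, 4, 5, 6), B = c(1, 2, 3, 4, 1, 2, 3, 4))
    colnames(m2) <- colnames(m)
    ds2 <- StateExpression(m2, rep(c("normal", "tumor"), each = 4), "toy")
    r2 <- edgeDysregulation(ds2, "A", "B")
    expect_equal(r2$ds, 0)
    expect_equal(r2$p_value, 1)

    # Welch oracle on noisy data
    set.seed(5)
    m3 <- matrix(rnorm(16, 7), 2, 8,
                 dimnames = list(c("A", "B"), colnames(m)))
    ds3 <- StateExpression(m3, rep(c("normal", "tumor"), each = 4), "toy")
    r3 <- edgeDysregulation(ds3, "A", "B")
    rs <- m3["A", ] - m3["B", ]
    tt <- t.test(rs[5:8], rs[1:4])
    expect_equal(r3$p_value, tt$p.value, tolerance = 1e-10)

    expect_error(edgeDysregulation(ds, "A", "ZZ"), "missing")
})

test_that("gene dysregulation scores sum significant |ds| and standardise", {
    set.seed(8)
    # hub with 10 strongly shifted targets; 12 null genes in a chain
    genes <- c("HUB", sprintf("T%02d", 1:10), sprintf("N%02d", 1:12))
    n <- 15
    m <- matrix(rnorm(length(genes) * 2 * n, 7, 0.5), length(genes),
                dimnames = list(genes, sprintf("S%02d", seq_len(2 * n))))
    m[sprintf("T%02d", 1:10), (n + 1):(2 * n)] <-
        m[sprintf("T%02d", 1:10), (n + 1):(2 * n)] + 1.5
    ds <- StateExpression(m, rep(c("normal", "tumor"), each = n), "toy")
    grn <- DirectedGRN(rbind(
        data.frame(regulator = "HUB", target = sprintf("T%02d", 1:10)),
        data.frame(regulator = sprintf("N%02d", 1:11),
                   target = sprintf("N%02d", 2:12))))
    res <- geneDysregulationScores(grn, ds)
    tab <- geneScores(res)

    # the planted hub attains the maximal z
    expect_equal(tab$gene[which.max(tab$z)], "HUB")

    # d equals the sum of significant |ds| over incident edges
    et <- edgeTable(res)
    for (g in c("HUB", "T01", "N05")) {
        inc <- et[et$regulator == g | et$target == g, ]
        expect_equal(tab$d[tab$gene == g],
                     sum(abs(inc$ds[inc$significant])), tolerance = 1e-12)
    }
    # gene with no significant incident edges scores 0
    noSig <- tab$gene[vapply(tab$gene, function(g)
        !any(et$significant[et$regulator == g | et$target == g]), TRUE)]
    if (length(noSig)) expect_true(all(tab$d[tab$gene %in% noSig] == 0))

    # z standardisation over scored genes
    expect_equal(mean(tab$z), 0, tolerance = 1e-9)
    expect_equal(sd(tab$z), 1, tolerance = 1e-9)

    # z invariant to the log base of the regulation strength
    resE <- geneDysregulationScores(grn, ds, base = exp(1))
    expect_equal(geneScores(resE)$z, tab$z, tolerance = 1e-9)

    # swapping state labels negates ds, leaves d and z unchanged
    dsSwap <- StateExpression(m, rep(c("tumor", "normal"), each = n), "toy")
    resSwap <- geneDysregulationScores(grn, dsSwap)
    expect_equal(edgeTable(resSwap)$ds, -et$ds, tolerance = 1e-12)
    expect_equal(geneScores(resSwap)$z, tab$z, tolerance = 1e-9)

    # explicit sum example
    expect_equal(sum(abs(c(-0.5, 1.5))), 2)
    tiny <- DirectedGRN(data.frame(regulator = c("HUB", "HUB"),
                                   target = c("T01", "T02")))
    expect_error(geneDysregulationScores(
        DirectedGRN(data.frame(regulator = "HUB", target = "ZZZ")), ds),
        "fewer than 3")
    expect_s4_class(geneDysregulationScores(tiny, ds), "DysregulationResult")
})

test_that("intersectHighZ keeps genes at or above the threshold everywhere", {
    mk <- function(z) new("DysregulationResult",
        geneTable = data.frame(gene = c("A", "B", "C"), d = 1, z = z,
                               n_edges = 1L),
        edgeTable = data.frame(), datasetId = "d", sigP = 0.05, base = 2)
    res <- list(mk(c(5.2, 6.0, 5.0)), mk(c(6.0, 5.5, 4.9)), mk(c(4.9, 7.0, 5.1)))
    # A has z = 4.9 in one dataset -> excluded; boundary z = 5 is included
    expect_equal(intersectHighZ(res), "B")
    expect_equal(intersectHighZ(res[1]), c("A", "B", "C"))
    expect_equal(intersectHighZ(res[c(1, 3)]), c("B", "C"))
})
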