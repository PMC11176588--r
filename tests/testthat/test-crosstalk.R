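test_that("readGMT parses the MSigDB format", {
    path <- withr::local_tempfile(fileext = ".gmt")
    writeLines(c("P1\tdesc one\tA\tB", "P2\tdesc two\tb\tC\tC"), path)
    pc <- readGMT(path)
    expect_equal(geneSets(pc), list(P1 = c("A", "B"), P2 = c("B", "C")))

    writeLines(c("P1\tdesc\tA", "BAD\tonly-desc"), path)
    expect_error(readGMT(path), "line 2")

    writeLines(character(), path)
    expect_warning(pcEmpty <- readGMT(path), "empty")
    expect_length(geneSets(pcEmpty), 0)
})

test_that("filterPathways applies size, category and overlap-retention rules", {
    pc <- PathwayCollection(
        sets = list(P1 = c("A", "B", "C", "D", "E"),
                    P2 = c("A", "B", "X", "Y", "Z"),
                    P3 = c("Q", "R", "S", "T", "U"),
                    SMALL = c("A", "B", "C", "D"),
                    DIS = c("A", "B", "C", "D", "E", "F")),
        categories = c(DIS = "human disease"))
    universe <- c(LETTERS, "AA")

    out <- filterPathways(pc, universe, excludedCategories = "human disease")
    # SMALL fails the 5-gene rule, DIS its category, P3 shares <2 genes with
    # any retained pathway; P1 and P2 share {A,B} and survive.
    expect_setequal(names(geneSets(out)), c("P1", "P2"))

    # a pathway with enough genes overall but <5 in the universe is dropped
    expect_warning(
        out2 <- filterPathways(pc, c("A", "B", "C", "D", "E", "F"),
                               excludedCategories = "human disease"),
        "no pathways")
    expect_false("P2" %in% names(geneSets(out2)))

    # overlap rule on a 3-pathway toy: P1-P2 overlap 1, so with no >=2
    # partner anywhere both are dropped (enumerated by hand)
    pc3 <- PathwayCollection(list(P1 = c("A", "B", "C", "D", "E"),
                                  P2 = c("E", "V", "W", "X", "Y"),
                                  P3 = c("K", "L", "M", "N", "O")))
    expect_warning(out3 <- filterPathways(pc3, universe), "no pathways")
    expect_length(geneSets(out3), 0)
})

test_that("classifyGene follows the exclusive/shared definitions", {
    A <- c("X", "S"); B <- c("Y", "S")
    expect_equal(classifyGene("S", A, B), "shared")
    expect_equal(classifyGene("X", A, B), "exclusive_A")
    expect_equal(classifyGene("Y", A, B), "exclusive_B")
    expect_equal(classifyGene("Z", A, B), "neither")
})

test_that("detectCrosstalk implements both criteria and their exclusions", {
    A <- c("a1", "a2"); B <- c("b1", "b2")

    ev <- detectCrosstalk(A, B, toyNet(c("a1", "a2"), c("b1", "b2")))
    expect_equal(ev$criterion, "bridge_pair")
    expect_equal(nrow(ev$pairs), 2L)

    # a single bridging pair is rejected as potential false positive
    expect_null(detectCrosstalk(A, B, toyNet("a1", "b1")))

    # shared-gene chain
    As <- c("a1", "s"); Bs <- c("b1", "s")
    ev2 <- detectCrosstalk(As, Bs, toyNet(c("a1", "s"), c("s", "b1")))
    expect_equal(ev2$criterion, "shared_gene")
    expect_equal(nrow(ev2$pairs), 2L)
    expect_true(all(vapply(seq_len(2), function(i)
        "shared" %in% c(ev2$pairs$role_a[i], ev2$pairs$role_b[i]), TRUE)))

    # a chain missing one side gives nothing
    expect_null(detectCrosstalk(As, Bs, toyNet("a1", "s")))

    # duplicated pathway: all genes shared, no exclusive genes, no edge
    expect_null(detectCrosstalk(A, A, toyNet(c("a1", "a2"), c("b1", "b2"))))

    # two pairs sharing one gene still satisfy criterion (i)
    ev3 <- detectCrosstalk(A, B, toyNet(c("a1", "a1"), c("b1", "b2")))
    expect_equal(ev3$criterion, "bridge_pair")
})

test_that("crosstalk detection matches the brute-force criteria evaluator", {
    set.seed(20)
    genes <- sprintf("g%02d", 1:12)
    for (rep in 1:40) {
        nPW <- sample(2:5, 1)
        sets <- lapply(seq_len(nPW), function(i)
            sample(genes, sample(3:6, 1)))
        names(sets) <- sprintf("P%d", seq_len(nPW))
        ed <- randomEdges(12, p = 0.15)
        ed$gene_a <- sprintf("g%02d", as.integer(sub("N", "", ed$gene_a)))
        ed$gene_b <- sprintf("g%02d", as.integer(sub("N", "", ed$gene_b)))
        net <- toyNet(ed$gene_a, ed$gene_b)
        for (i in seq_len(nPW - 1)) for (j in seq(i + 1, nPW)) {
            want <- bruteCrosstalk(sets[[i]], sets[[j]], edgeTable(net))
            got <- detectCrosstalk(sets[[i]], sets[[j]], net)
            expect_equal(!is.null(got), want$crosstalk,
                         info = sprintf("rep %d pair %d-%d", rep, i, j))
            # symmetry in the pathway arguments
            gotBA <- detectCrosstalk(sets[[j]], sets[[i]], net)
            expect_equal(is.null(got), is.null(gotBA))
            if (!is.null(got)) {
                expect_equal(got$criterion %in% c("bridge_pair", "both"),
                             want$critI)
                expect_equal(got$criterion %in% c("shared_gene", "both"),
                             want$critII)
                if (!is.null(gotBA))
                    expect_equal(nrow(got$pairs), nrow(gotBA$pairs))
            }
        }
    }
})

test_that("buildCrosstalkNetwork assembles edges, PathGeNet and nodes", {
    # 3 pathways, 6 genes, one planted bridge between P1 and P2
    pc <- PathwayCollection(list(P1 = c("A1", "A2"), P2 = c("B1", "B2"),
                                 P3 = c("C1", "C2")))
    net <- toyNet(c("A1", "A2", "C1"), c("B1", "B2", "C2"))
    xt <- buildCrosstalkNetwork(pc, net)
    expect_equal(nrow(edgeTable(xt)), 1L)
    expect_equal(edgeTable(xt)$pathway_a, "P1")
    expect_equal(edgeTable(xt)$pathway_b, "P2")
    expect_equal(nrow(pathGeNet(xt)), 2L)
    expect_setequal(xt@nodes, c("P1", "P2"))

    # PathGeNet edges are a subset of the co-expression network
    pg <- pathGeNet(xt)
    expect_true(all(paste(pg$gene_a, pg$gene_b) %in%
                    paste(edgeTable(net)$gene_a, edgeTable(net)$gene_b)))

    # empty co-expression network gives an empty cross-talk network
    empty <- buildCrosstalkNetwork(pc, toyNet(character(), character()))
    expect_equal(nrow(edgeTable(empty)), 0L)
    expect_equal(nrow(pathGeNet(empty)), 0L)

    # monotonicity: adding co-expression edges never removes a cross-talk edge
    bigger <- toyNet(c("A1", "A2", "C1", "A1"), c("B1", "B2", "C2", "C1"))
    xt2 <- buildCrosstalkNetwork(pc, bigger)
    expect_true(all(paste(edgeTable(xt)$pathway_a, edgeTable(xt)$pathway_b) %in%
                    paste(edgeTable(xt2)$pathway_a, edgeTable(xt2)$pathway_b)))

    # deleting shared genes can only disable criterion (ii)
    As <- c("a1", "a2", "s"); Bs <- c("b1", "b2", "s")
    netI <- toyNet(c("a1", "a2"), c("b1", "b2"))
    withShared <- detectCrosstalk(As, Bs, netI)
    without <- detectCrosstalk(setdiff(As, "s"), setdiff(Bs, "s"), netI)
    expect_equal(withShared$criterion, "bridge_pair")
    expect_equal(without$criterion, "bridge_pair")
})
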