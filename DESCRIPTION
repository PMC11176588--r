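Package: xtalknet
Title: State-Dependent Pathway Cross-Talk Networks from Gene Co-Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs state-dependent (normal versus tumor) gene
    co-expression networks across multiple expression datasets, derives a
    sign-consistent consensus network, and detects pathway cross-talk from
    co-expressed gene pairs bridging pathway gene sets under two explicit
    evidence criteria, together with the interface gene network (PathGeNet).
    Compares networks between states, ranks key genes by betweenness
    centrality, scores per-gene dysregulation over a directed gene regulatory
    network from state-averaged log expression ratios, and evaluates the
    prognostic value of gene clusters with Cox-derived risk scores, median
    stratification, Kaplan-Meier curves and the log-rank test. Includes a
    seed-reproducible synthetic study generator with planted ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    survival,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
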