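---
title: "Methods: state-dependent pathway cross-talk, dysregulation scoring and risk stratification"
author: "xtalknet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent pathway cross-talk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalknet)
```

# Overview

`xtalknet` implements an integrative network analysis for paired
normal/tumor expression studies: state-dependent consensus co-expression
networks across several datasets, rule-based pathway cross-talk detection
with its interface gene network (PathGeNet), normal-versus-tumor network
comparison with betweenness-based key-gene ranking, a per-gene dysregulation
score over a directed gene regulatory network (GRN), and Cox risk-score
survival stratification. This vignette records the model, its assumptions,
the tunable parameters, the numerical conventions, and the design choices
made where the procedure was genuinely underdetermined.

# Input model and assumptions

Expression is assumed to be a normalised, log2-scale genes × samples matrix
per dataset (microarray intensities or log-transformed RNA-seq abundances),
with every sample labelled `normal` or `tumor`. The package does not
normalise: cross-platform harmonisation is limited to restricting all
datasets to their common genes (`intersectGenes()`). Pathways are plain gene
sets (GMT); no pathway topology is used. The GRN is a user-supplied directed
edge list; edges labelled as predicted interactions are dropped at ingestion
by default.

# Stage-by-stage model

## Differential expression

`differentialExpression()` reports, per gene, `log2fc = mean(tumor) -
mean(normal)` on the log2 values and a two-sided Welch t-test p-value. The
Welch test is a deliberate, documented choice for this package: it keeps the
stage self-contained on already-normalised matrices, and externally computed
tables (e.g. from moderated-statistics pipelines) can be substituted
anywhere a DE table is consumed via the three-column format
(`gene`, `log2fc`, `p_value`). No multiple-testing correction is applied to
DE p-values: the selection rule downstream is a raw `p < 0.01` in *every*
dataset combined with a cross-dataset mean `|log2fc| >= 0.5`
(`signatureGenes()`), and the per-dataset consistency requirement is itself
a strong filter. Degenerate genes (identical values in both states) get
`log2fc = 0, p = 1`; a zero-variance gene whose means differ gets `p = 0`.

## Co-expression and consensus

Within each state of each dataset, `stateNetwork()` scores all gene pairs
with the Pearson correlation and the exact t-transform p-value
(`t = r sqrt((n-2)/(1-r^2))`, `n - 2` df; `|r| = 1` maps to `p = 0`).
Defaults `rMin = 0.7`, `pMax = 0.05`. The threshold is read as `|r| >= 0.7`,
admitting both signs — this is forced by the consensus rule, which
explicitly accepts positive or negative patterns so long as the sign agrees
across all datasets. Pair p-values are likewise uncorrected by default; at
0.7 and 20 samples per state the correlation threshold, not the p-value, is
binding. Zero-variance genes are dropped from pairing with a warning rather
than failing the run.

`consensusNetwork()` keeps pairs present in every dataset's network with a
consistent sign. The consensus `r` is the arithmetic mean (simple and
sign-preserving under the consistency filter); the stored p-value is the
maximum across datasets, i.e. the most conservative of the per-dataset
values, since no combination rule is canonical here.

## Pathway filtering

`filterPathways()` applies, in order: intersection with the measured gene
universe; a minimum surviving set size (`minGenes = 5`); category exclusion
(intended for disease/drug-development collections, which are redundant with
the phenotype under study); and a retention rule requiring each pathway to
share at least two genes with at least one other retained pathway. The last
rule has two defensible readings — a pairwise candidacy condition or a
node-retention condition. The pairwise reading would contradict cross-talk
criterion (i), which needs no shared genes at all, so the retention reading
is implemented, applied once (not iterated to a fixpoint). This is a
documented interpretation, not an assertion about intent.

## Cross-talk criteria

For a pathway pair (A, B), gene roles are taken relative to the pair:
exclusive to A (`A \ B`), exclusive to B (`B \ A`), or shared. An edge is
reported when at least one criterion holds:

* **(i) bridge pairs** — at least two *distinct* co-expressed pairs, each
  joining an A-exclusive to a B-exclusive gene. The two pairs may share a
  gene: the stated purpose of the rule is only to exclude single-pair
  evidence, and the quantifiers do not forbid a common endpoint.
* **(ii) shared gene** — some shared gene co-expressed with at least one
  A-exclusive gene and at least one B-exclusive gene.

Detection is symmetric in A and B, and a pathway paired with its own copy
can never produce an edge (no exclusive genes). The evidence table records
every supporting pair with its endpoint roles; when both criteria hold the
edge is labelled `both`. The PathGeNet is the union of all evidence pairs
over all cross-talk edges and is, by construction, a subgraph of the
consensus network. Pathway node counts are reported over non-isolated nodes.

## Comparison and key genes

`networkDifference()` is exact set algebra on canonically ordered unordered
pairs, at either the pathway or the gene level; the three parts partition
the union of the inputs. Key genes are ranked by unnormalised shortest-path
betweenness (Brandes, via igraph, unit weights, unordered-pair counting)
within a connected component's induced subgraph. Since only ranks are
consumed, the normalisation constant is irrelevant. Ties are broken
lexicographically and a tie crossing the rank-k boundary is messaged;
components are ordered by size, then by smallest member, so results are
invariant to insertion order.

## Dysregulation over a directed GRN

For an edge i→j, the per-sample regulation strength is the log ratio of
linear-scale expression, `r_ij = log2(E_i / E_j)`. Stored log2 matrices are
exponentiated first — applying the ratio to already-logged values would be a
double log; on log2 input this reduces to the difference of log2 values. The
dysregulation strength `ds_ij` is the tumor mean minus the normal mean of
`r_ij`; per-edge significance uses a two-sided Welch t-test on the
per-sample values (`sigP = 0.05`), the package's documented stand-in for an
unnamed significance rule. The per-gene score `d_i` sums `|ds_ij|` over all
significant incident edges, upstream and downstream. The absolute value
prevents a gene dysregulated in both directions from cancelling to zero and
matches the use of a one-sided high-Z cutoff downstream; signed summation is
available (`absolute = FALSE`). Z-scores standardise `d` across all genes
with at least one measurable edge, per dataset; they are invariant to the
log base (a base change rescales all `ds` by one constant). If every score
is identical (e.g. no significant edge anywhere in a null dataset), no gene
deviates and all Z are defined as 0 rather than NaN. Genes with `Z >= 5`
(inclusive) in every dataset are reported by `intersectHighZ()`.

## Survival

Cox proportional-hazards fitting is delegated to `survival::coxph` — it is
routine statistics, and delegating it keeps the package's own survival code
(Kaplan–Meier and log-rank) small enough to verify against closed forms.
Risk scores are `sum_i Exp_i * beta_i`; the cohort is split at the *median*
score with ties (including the median sample at odd n) assigned to the
low-risk group — the tie rule is a documented convention, configurable by
supplying coefficients and scores directly. The Kaplan–Meier estimator steps
only at event times, with censored times reducing the risk set (ties at a
time count the censored individuals as still at risk at that time, matching
the standard convention). The log-rank statistic uses the hypergeometric
variance with the usual `(n - d)/(n - 1)` tie correction on 1 df. Overall
survival is the assumed endpoint; time units are whatever the input table
uses.

# The synthetic generator

`generateStudy()` emulates the *structure* of a multi-dataset paired-state
study: several independent datasets with a shared gene universe, planted
sign-consistent co-expression modules that exist only in the designated
state (so cross-talk rewires between states), pathways in an overlapping
chain, a directed GRN with shifted hub edges, and a survival cohort from an
exponential proportional-hazards model with independent uniform censoring.

Defaults and why:

* **3 datasets, 20 samples per state** — three independent discovery
  cohorts with cohort sizes at the scale of paired-tissue microarray
  studies. At `rho = 0.9` and n = 20, a planted pair passes `|r| >= 0.7` in
  any one dataset with probability ≈ 0.99, so multi-pair evidence survives
  the triple-intersection consensus with high probability.
* **`rho = 0.9`** within-module correlation: strong co-regulation, well
  above the detection threshold but below degeneracy.
* **Planting redundancy** — criterion-(i) cross-talk is planted as 3
  bridging two-gene modules (the criterion needs 2) and criterion-(ii) as 2
  shared-gene chains. Real cross-talks carry many supporting pairs; planting
  the bare minimum would make recovery hinge on a single
  threshold-crossing event rather than on the method.
* **`noiseSd = 0.5`** log2 units within state — typical within-group
  variability for normalised array data.
* **GRN**: 2 hubs × 10 targets shifted by `delta = 1` log2 unit in tumor,
  plus 30 background genes with 40 unshifted random edges so the Z
  standardisation has a realistic null bulk. At these settings the per-edge
  Welch power is ≈ 0.99, so a hub accumulates `d ≈ 10` against a background
  near 0.
* **Survival**: 100 patients, five cluster genes with coefficients
  `(0.8, -0.6, 0.5, -0.4, 0.3)` on standardised expression, baseline hazard
  0.1, uniform censoring on (0, 30) giving ≈ 30 % censoring.

`generateNullStudy()` keeps the full layout (same pathways, same GRN
topology, same cohort sizes) but plants nothing: genes independent, no
ratio shift, survival independent of expression. It is the calibration
counterpart for every recovery claim, including the "`rho = 0`" behaviour:
the consensus network of a null study is empty in essentially every seed.

What the generator does **not** emulate: platform-specific noise
distributions, batch effects, probe-level artefacts, correlated background
structure beyond the planted modules, non-proportional hazards, or
informative censoring. Passing the recovery and calibration suites therefore
demonstrates correctness of the algorithms under the generating model, not
performance on real microarray or RNA-seq cohorts.

# Calibration design

Two calibration facts are worth recording explicitly.

First, the type-I error of the risk-stratification pipeline is checked on
null cohorts with a *single-gene* cluster run through the full pipeline
(Cox fit → risk score → median split → log-rank). With one gene the median
split is the same sample partition regardless of the fitted coefficient (a
monotone transform of the covariate), so the log-rank test is exact at its
nominal level and the check is a genuine calibration of the pipeline's
test. With a multi-gene cluster, fitting the Cox model and then testing the
median split of its in-sample risk score on the same data is
anti-conservative by construction — a fit-then-test bias inherent to this
widely used procedure (also present in web tools that fit and stratify on
one cohort), not an implementation artefact. On real data the remedy is to
carry coefficients to an independent validation cohort, which the package
supports by passing fixed `beta` to `evaluateCluster()`.

Second, the null rate of high-Z calls is assessed at the study level — a
null seed counts as a false call if any gene reaches `|Z| >= 5` in *every*
dataset — because the cross-dataset intersection is the pipeline's actual
decision rule for key dysregulated genes. Per-dataset `|Z| >= 5` excursions
do occur under the null (high-degree nodes have more chances to accumulate
falsely significant edges), which is precisely why the intersection rule is
the appropriate guard.

# Numerical conventions

* Unordered pairs are stored canonically (`gene_a < gene_b`); all set
  operations key on the canonical pair.
* `|r| = 1` maps to `p = 0`; r is clamped to [-1, 1] before the t-transform.
* Welch df follow the Satterthwaite formula; degenerate rows (both variances
  zero) give `p = 1` when means agree, `p = 0` otherwise.
* Betweenness ties at the rank-k boundary break lexicographically and are
  messaged; component ordering is (size desc, smallest member).
* Duplicate gene rows collapse by mean at ingestion (deterministic and
  order-independent); gene symbols are upper-cased in pathway and GRN
  inputs.
* Z-scores with zero variance of `d` are 0 by definition (see above).
* Test problem sizes: oracle-equivalence checks run on toys of up to 12
  genes / 5 pathways / 8 graph nodes (where exhaustive enumeration is
  exact); recovery uses 50 generator seeds and calibration 200 (log-rank)
  and 100 (high-Z) seeds — sizes at which the binomial uncertainty of the
  measured rates is small relative to the bands being checked.

# Known limitations

* The Welch DE test is not a moderated test; for small cohorts a
  moderated-variance pipeline will be better powered. Import its table
  instead.
* Consensus requires presence in *all* datasets; there is no "k of m"
  relaxation.
* Cross-talk uses gene sets only; pathway topology, edge direction within
  pathways, and shared-component mechanisms other than co-expression are out
  of scope.
* The GRN is taken as given; no network inference is performed.
* In-sample multi-gene risk stratification is anti-conservative (see
  Calibration design); interpret single-cohort p-values accordingly.
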