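# xtalknet

State-dependent pathway cross-talk networks from gene co-expression, with
GRN-based gene dysregulation scoring and risk-score survival stratification.

## The problem

Biological pathways do not act in isolation: genes from different pathways
are co-regulated, and the pattern of this inter-pathway coordination
("cross-talk") rewires between a normal tissue state and a tumor state.
`xtalknet` is for systems-biology analysts who have genes × samples
expression matrices for paired normal/tumor cohorts (several independent
datasets), pathway gene sets in GMT format, optionally a directed gene
regulatory network and survival follow-up, and who want to ask:

* which pathway pairs are in cross-talk in each state, and which gene pairs
  carry the evidence (the interface network, *PathGeNet*);
* which cross-talks and gene interactions are gained, lost or conserved
  between states, and which genes are topologically central to them;
* which genes are most dysregulated in their regulatory interactions; and
* whether an identified gene cluster separates high-risk from low-risk
  patients.

## The model

**Co-expression.** Within each state of each dataset, every gene pair is
scored by the Pearson correlation r with the two-sided p-value from
`t = r sqrt((n-2)/(1-r^2))`; pairs with `|r| >= 0.7` and `p < 0.05` are
co-expressed. The consensus network keeps pairs co-expressed with the same
sign of r in *every* dataset.

**Cross-talk.** For pathways A and B, with gene roles taken relative to the
pair (exclusive to A, exclusive to B, or shared), an edge A–B requires at
least one of:

* **(i)** two distinct co-expressed pairs, each joining an A-exclusive gene
  to a B-exclusive gene;
* **(ii)** a shared gene co-expressed with at least one A-exclusive and at
  least one B-exclusive gene.

A single bridging pair is never sufficient, which suppresses false-positive
cross-talk from isolated correlations. The union of all supporting gene
pairs is the PathGeNet; its connected components are ranked by unnormalised
betweenness centrality to nominate key genes.

**Dysregulation.** Over a directed GRN, the regulation strength of an edge
i→j in one sample is `r_ij = log2(E_i / E_j)` on linear-scale expression.
The dysregulation strength is `ds_ij = mean_tumor(r_ij) - mean_normal(r_ij)`
(Welch-tested), and the per-gene dysregulation score sums `|ds_ij|` over all
significant incident edges, upstream and downstream. Scores are standardised
to Z across genes within a dataset; genes with `Z >= 5` in every dataset are
the key dysregulated genes.

**Prognosis.** A gene cluster is evaluated by a multivariate Cox fit
(`survival::coxph`), per-sample risk scores `sum_i Exp_i * beta_i`, a median
split into high/low risk, Kaplan–Meier curves per group and the two-group
log-rank test.

## Worked example

The built-in generator emits a three-dataset study (20 normal + 20 tumor
samples each, 120 genes) with two planted cross-talks, two dysregulated GRN
hub genes and a five-gene prognostic cluster:

```r
library(xtalknet)

study <- generateStudy(syntheticConfig(seed = 1))
cons  <- consensusNetwork(lapply(study$datasets, stateNetwork, state = "tumor"))
cons
#> CoexpressionNetwork [tumor]: 9 edges, 12 genes (|r|>=0.7, p<0.05; datasets: SIM1,SIM2,SIM3)

pcF <- filterPathways(study$pathways, rownames(study$datasets[[1]]))
xt  <- buildCrosstalkNetwork(pcF, cons)
edgeTable(xt)
#>   pathway_a pathway_b   criterion n_support_pairs
#> 1       PW1       PW2 bridge_pair               3
#> 2       PW3       PW4        both               6

dys <- lapply(study$datasets, function(d) geneDysregulationScores(study$grn, d))
head(geneScores(dys[[1]])[order(-geneScores(dys[[1]])$z), ], 3)
#>    gene         d         z n_edges
#> 1 G0063 12.176156 5.1063829      10
#> 2 G0064 10.238917 4.2293724      10
#> 4 G0066  1.445814 0.2486342       1

ev <- evaluateCluster(study$survival$expr, study$survival$surv)
ev$model
#> RiskModel: 5 genes, 100 samples (high=50, low=50), median threshold 0.04638
ev$logrank
#> chi2 = 39.08, p = 4.06e-10
```

Both planted cross-talks are recovered (PW1–PW2 by bridging pairs with 3
supporting gene pairs, PW3–PW4 through its shared genes, which here also
satisfies the bridging criterion) and nothing else is reported. The planted
hub genes G0063/G0064 (10 shifted regulatory edges each) top the
dysregulation ranking, and the prognostic cluster splits the cohort into
risk groups with clearly separated survival. `runDiscovery()` chains all of
these stages, writes TSV/SIF artifacts and a JSON manifest with the counts
surviving every filter.

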