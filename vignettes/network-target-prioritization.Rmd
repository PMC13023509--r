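---
title: "Methods: network-based target prioritization with netprior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based target prioritization with netprior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprior)
```

## The problem

A recurring question in computational pharmacology is which protein a
bioactive compound acts through. A common strategy combines three sources
of evidence: (i) a transcriptomic contrast between exposed and control
samples, screened for differentially expressed genes (DEGs); (ii) the
compound's predicted protein targets, retrieved from several prediction
databases and intersected with the DEGs; and (iii) the topology of the
protein–protein interaction (PPI) network spanned by those intersection
targets, in which the most central node is nominated as the working
hypothesis for the compound's target. netprior implements this strategy as
a tested, reproducible pipeline over plain-text inputs (a DE summary
table, gene lists, a GMT gene-set collection, an expression matrix and a
whitespace-delimited edge list), with a seeded synthetic-data module so
that every stage can be exercised and verified without any external
download.

## DEG screening

The screen consumes a precomputed per-gene table of log2 fold changes and
p-values (fitting the DE model itself, e.g. with a negative-binomial
count model, is out of scope). When no adjusted p-value column is
supplied, Benjamini–Hochberg step-up adjustment is applied via
`stats::p.adjust`; Bonferroni and a pass-through are available for
sensitivity analyses. A gene is called up-regulated when
`log2fc > lfc_cut` and `padj < alpha`, down-regulated symmetrically; both
inequalities are **strict**, so a gene sitting exactly at either cutoff is
excluded. Defaults are `lfc_cut = 0.5` and `alpha = 0.05`. Genes with
missing p-values are removed before adjustment (mirroring the independent
filtering of upstream DE tools) and the exclusion count is logged.

## Enrichment statistics

**Over-representation (ORA).** For query set $q$, gene set $m$ and
universe $N$ (all sets intersected with the universe first), the p-value
is the hypergeometric upper tail $P(X \ge k)$ for the observed overlap
$k$. Adjusted p-values are BH across terms; results are sorted by p-value
with a term-name tie-break. The test suite verifies the tail against
exhaustive subset enumeration for every configuration with a universe of
at most 15 genes.

**GSEA.** The weighted Kolmogorov–Smirnov running sum over a ranked gene
list: at a set member the sum rises by $|s_i|^p / \sum_{hits} |s_j|^p$,
at a non-member it falls by $1/(N - N_{hits})$; the enrichment score (ES)
is the signed maximum deviation from zero. The default ranking metric for
a DE table is the log2 fold change, descending (a signed $-\log_{10} p$
metric is available). Significance uses a **gene-label permutation
null**: membership labels are reshuffled `n_perm` times and the two-sided
p-value is $(1 + \#\{|ES_{perm}| \ge |ES_{obs}|\})/(n_{perm}+1)$, which
is never exactly zero. Rank positions use a stable sort with a
lexicographic gene tie-break, so all rankings are deterministic. Two
degenerate cases are defined by convention: a set covering the whole list
scores $ES = +1$, and all-zero hit weights fall back to equal weights.

**ssGSEA.** Per-sample scores follow the integrated-difference form: genes
are ordered by expression (descending, gene tie-break for positions;
average ranks for tied weights), ranks $N..1$ become weights
$\mathrm{rank}^\alpha$ with $\alpha = 0.25$, and the score is
$\sum_i [P^w_{in}(i) - P_{out}(i)]$, the accumulated gap between the
weighted CDF of member positions and the unweighted CDF of non-member
positions. No cross-sample min–max rescaling is applied, so each sample's
score depends only on its own ranks — the suite verifies invariance under
strictly monotone per-sample transforms. A set with no member in the
matrix, or one covering every gene (no non-members), is an error.

**Group comparison.** Per-term scores are compared between two groups
with a two-sided Welch t-test (chosen for small continuous scores such as
a 4-vs-4 design; Mann–Whitney by option). Groups of fewer than two
samples are rejected; two constant, equal groups return statistic 0 and
p = 1, since the t statistic is 0/0 there.

## Target integration

Predicted-target lists from several sources are unioned with
deduplication and intersected with the DEG set. Gene symbols are treated
as case-sensitive opaque strings; an `uppercase` option applies
uppercasing at read time as the harmonization mechanism when sources mix
capitalization conventions. The report keeps per-source sizes, the
pairwise source-overlap matrix and the up/down direction of each
intersected target as metadata.

## Centrality consensus

Nine node-level measures are computed on the undirected, unweighted PPI
network: Degree, MNC (largest connected component of the open
neighborhood), MCC (sum of $(|C|-1)!$ over maximal cliques $C$ containing
the node), EPC (mean component fraction over random edge-retention
realizations), Betweenness (unnormalized shortest-path fraction), Stress
(shortest-path count), EcCentricity (component size over eccentricity),
Closeness and Radiality. Choices where definitions vary in the field:

* **Closeness** is harmonic by default ($\sum_w 1/d(v,w)$, unreachable
  nodes contributing 0) so disconnected graphs produce finite scores; a
  classic within-component form is available by option.
* **Radiality** uses the component diameter and normalizes by $n - 1$
  over the whole graph, so nodes in small components score low.
* **EPC** has no canonical parameterization; the defaults are 1000
  realizations with edge-retention probability 0.5, both exposed and
  recorded in outputs. Realizations draw retention masks in a canonical
  edge order (endpoints sorted within an edge, edges sorted
  lexicographically), which makes the estimator exactly reproducible for
  a given seed. With retention probability 1 the score reduces exactly to
  the component-size fraction.
* **MCC** counts maximal cliques of any size, so a node whose maximal
  cliques are all single edges scores its degree, and an isolated node
  scores $0! = 1$ (its singleton clique).

Hub nomination takes the **tie-expanded top-k** (default $k = 3$) per
measure — if the k-th score is tied, every gene at that score is included
— and intersects the nine sets. Tie expansion keeps the consensus
deterministic without imposing an arbitrary order among tied nodes, at
the cost of occasionally admitting more than $k$ genes per method. The
consensus is invariant to method evaluation order.

All nine measures are validated against a brute-force oracle
(simple-path enumeration, subset enumeration for cliques, reachability
closure for components) on 200 seeded random connected graphs of up to 7
nodes.

## Random walk with restart

The Monte Carlo walker starts at a source node; at each transition it
returns to its source with probability $r$ (default 0.1), otherwise moves
to a uniformly random neighbor; a neighborless node forces a restart.
Each walk makes up to 100 transitions (default) and 10,000 walks are run
per source (default). **Every occupied position is tallied, including the
start and post-restart landings**, so each walk contributes
$1 + \texttt{max\_steps}$ tallies and the visit fractions estimate the
occupancy measure described by the stationary personalized PageRank
(PPR) vector. Restart returns the walker to its own source (standard
RWR); three source modes are exposed — every node, one uniformly chosen
node, or a caller-supplied set (e.g. the target–DEG intersection) —
because published descriptions of the procedure are ambiguous about the
seeding. Per-source random substreams are derived from (seed, source), so
results are reproducible and independent of source order.

The exact counterpart `ppr_exact` solves
$\pi = r\,s + (1-r)\,W^\top \pi$ by power iteration (uniform-neighbor
transition $W$, neighborless nodes redirecting to the source
distribution $s$, L1 tolerance $10^{-12}$, error on non-convergence).
On the two-node graph the closed form is $\pi_A = r/(1-(1-r)^2)$, which
equals $0.1/0.19$ at the default restart probability; the test suite
checks the power iteration against it to $10^{-9}$, against igraph's
personalized PageRank on random graphs, and checks the Monte Carlo
estimate against the exact vector in total variation (≤ 0.05) and
Spearman correlation (≥ 0.9). The small transient bias of the finite
walk (the early steps overweight the source's neighborhood) is well
inside those bands at the default parameters.

## The synthetic-data module

The generators encode the study conditions the pipeline assumes, with one
master seed split into named substreams (so, e.g., the DE table is
unchanged if only the network parameters move):

* **DE table** — `n_genes = 5000`, a planted fraction `frac_de = 0.1`
  of DE genes with mean effect `effect_mu = 2` on the log2 scale and
  null spread `null_sd = 0.5`. Null genes draw log2FC from
  $N(0, \sigma)$ and p-values independently from Uniform(0,1); planted
  genes draw log2FC $= \pm\mu + N(0,\sigma)$ and take the two-sided
  normal tail of $z = |log2FC|/\sigma$ as their p-value, so larger
  effects give smaller p-values. A z-score construction is used rather
  than count simulation because the pipeline consumes DE summaries, not
  reads.
* **Expression matrix** — two groups of 4 samples (the emulated design),
  baseline $N(0,1)$, and an additive shift `set_shift = 5` applied to a
  planted gene set in group B. This is a rank-signal generator for
  ssGSEA; it does not emulate count overdispersion, library-size or
  batch effects.
* **PPI network** — preferential-attachment growth (`n_nodes = 20`,
  `attach_m = 2`; heavy-tailed degrees like real PPI subgraphs, and a
  connected simple graph with exactly `attach_m * (n_nodes - attach_m)`
  edges), then a planted hub: a node chosen uniformly among
  non-maximum-degree candidates receives `hub_extra_edges = 12` extra
  edges to non-neighbors. Candidates are restricted to nodes with enough
  non-neighbors and with final degree strictly above the previous
  maximum plus one, which makes the hub the unique maximum-degree node
  by construction (an error is raised when no candidate exists rather
  than silently degrading the plant). The 20-node scale mirrors the
  small intersection-target networks this analysis runs on in practice.
* **Target lists** — 4 pseudo-sources of 30 symbols, each containing a
  common planted core with the remainder sampled from the gene universe,
  reproducing the partially-overlapping structure of real prediction
  databases.

Because the generators plant known answers, recovery statements are
testable: the consensus and the RWR ranking recover the planted hub in
at least 95/100 and 90/100 seeded replicates respectively, the DEG
screen's false discovery proportion under the global null stays below
0.07, and the ssGSEA group test detects the planted shift in at least
95/100 replicates. Passing these tests shows the machinery is correct
and calibrated under the generator's idealized assumptions
(independent genes, clean rank signal, a single dominant hub); it does
not certify performance on real data with correlated expression,
annotation errors or incomplete interactomes.

## Numerical and testing choices

* All rankings order by descending score with a lexicographic gene
  tie-break; outputs are therefore byte-identical across repeated runs
  with the same seed.
* Scores are serialized with 15 significant digits, so write/read round
  trips preserve at least 12.
* The GSEA null-calibration check estimates the type-I error from 1000
  null replicates (estimator standard error ≈ 0.007) so the estimate is
  reproducibly inside the 0.05 ± 0.02 calibration band; with only a few
  hundred replicates the Monte Carlo error of the check itself would be
  comparable to the band.
* The centrality-oracle suite runs the EPC comparison at 200
  realizations per graph: equality is checked per realization, so the
  realization count only sets how many are compared.
* The pipeline tests run a scaled-down configuration (400 genes, 300
  walks, 49 permutations) — the stage logic is size-independent and the
  statistical properties are covered at full scale by the dedicated
  acceptance tests.

## Limitations

* The PPI network is unweighted; interaction confidence scores present
  in an edge list are ignored.
* The permutation GSEA uses a gene-label null, not phenotype
  permutation, and no multilevel refinement for very small p-values.
* ssGSEA omits kernel density smoothing and cross-sample normalization
  by design; scores are comparable across samples only through their
  common rank construction.
* Identifier harmonization across target sources is limited to optional
  uppercasing; orthology mapping or alias resolution is out of scope.
* Monte Carlo RWR at the default parameters is an estimator; for exact
  rankings on small networks use `ppr_exact` directly.
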