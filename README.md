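# netprior

Network-pharmacology target prioritization in R: differential-expression
screening, enrichment scoring, multi-source target integration, and hub
nomination on a protein–protein interaction (PPI) network by a
nine-centrality consensus and random walk with restart.

## What it does

Given (a) a per-gene differential-expression summary (log2 fold change,
p-value), (b) predicted-target gene lists from several sources, (c) a PPI
edge list and optionally (d) an expression matrix plus gene sets in GMT
format, the package nominates candidate targets in four steps:

1. **DEG screen** — Benjamini–Hochberg adjustment, then the cutoff rule
   |log2FC| > 0.5 and adjusted p < 0.05 (both strict).
2. **Target integration** — deduplicated union of the source lists,
   intersected with the DEGs.
3. **Hub consensus** — nine topological centralities on the PPI network
   (Degree, MNC, MCC, EPC, Betweenness, Stress, EcCentricity, Closeness,
   Radiality); the tie-expanded top-3 sets per measure are intersected.
4. **Random walk with restart (RWR)** — 10,000 walks per source, up to
   100 steps, restart probability 0.1; node visit fractions estimate the
   personalized PageRank vector
   π = r·s + (1 − r)·Wᵀπ, for which `ppr_exact()` provides the
   closed-form power-iteration solution used as the Monte Carlo oracle.

Enrichment support: hypergeometric over-representation analysis,
weighted-KS GSEA with a gene-label permutation null, per-sample ssGSEA
scores, and a Welch test comparing ssGSEA scores between two groups.

A seeded synthetic-data module (`synthetic_spec()`, `gen_de_table()`,
`gen_expression()`, `gen_ppi()`, `gen_target_lists()`) generates inputs
with planted signal — a known DE gene set, a known expression-shifted gene
set, and a PPI network with a known unique hub — so the full pipeline runs
and is verified without any external download.

## Worked example

```r
library(netprior)

spec <- synthetic_spec(seed = 1)          # 5000 genes, 10% planted DE,
de   <- gen_de_table(spec)                # 20-node network with planted hub
part <- screen_degs(de$table)
part
#> DEG partition: 448 DEGs ( 215 up, 233 down ) of 5000 genes

net  <- gen_ppi(spec)
net$hub
#> [1] "N09"

cons <- consensus(net$graph, k = 3, seed = 1)
cons
#> Centrality consensus over 9 methods (k = 3 ): N05, N09

rwr <- mc_rwr(net$graph, seed = 1)        # defaults: 10,000 walks x 100 steps
head(rwr$ranking, 3)
#>   gene      score
#> 1  N09 0.13573931
#> 2  N05 0.09099371
#> 3  N06 0.07922728
```

The screen recovers most of the planted 10% of DE genes (441 of the 500
planted genes, plus 7 false positives kept rare by BH control). Both the
centrality consensus and the RWR ranking place the planted hub `N09`
first: it survives the top-3 cut of all nine centralities and receives
the largest walk visit fraction (0.136). The exact two-node closed form
illustrates what the walk estimates:

```r
ppr_exact(ppi_network("A", "B"), "A", restart_prob = 0.1)
#>   gene     score
#> 1    A 0.5263158   # = 0.1 / 0.19
#> 2    B 0.4736842
```

An end-to-end run over files is one call (or one shell command via
`inst/cli/netprior.R`):

```r
run_pipeline(pipeline_config(outdir = "run1", seed = 1))
```

which simulates the inputs, screens DEGs, integrates targets, ranks hubs,
runs the walk and writes per-stage TSV outputs plus a `manifest.json`
with parameters and checksums.

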