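Package: netprior
Title: Network Pharmacology Target Prioritization with Centrality
    Consensus and Random Walk with Restart
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nominating candidate drug targets from transcriptomic
    and protein-protein interaction (PPI) data. Implements differential
    expression screening with Benjamini-Hochberg adjustment, hypergeometric
    over-representation analysis, weighted Kolmogorov-Smirnov gene set
    enrichment (GSEA) with a gene-label permutation null, single-sample GSEA
    scoring, multi-source target union and intersection with differentially
    expressed genes, a nine-measure topological centrality consensus for hub
    screening (Degree, MNC, MCC, EPC, Betweenness, Stress, EcCentricity,
    Closeness, Radiality), Monte Carlo random walk with restart, and its
    closed-form personalized PageRank counterpart. A seeded synthetic-data
    module generates differential-expression tables, expression matrices,
    scale-free-like PPI networks with a planted hub, and overlapping target
    lists, so the full pipeline runs and is verified without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
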