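Package: nibbsr
Title: Phenotype-Biased Metabolic Subgraph Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of organism-specific metabolic networks to
    identify metabolic subsystems biased toward phenotype-expressing
    organisms. Implements the NIBBS-Search heuristic (greedy seed-set
    generation and delta-controlled seed expansion), the exact MBS-Enum
    enumerator of maximally-biased subgraphs with a brute-force oracle, an
    upper-tail hypergeometric phenotype-bias metric and pathway enrichment
    test, Jaccard-based approximation scoring against the exact subgraph set
    with empirical permutation p-values, per-enzyme t-test and mutual
    information baselines, and synthetic data generators with planted
    phenotype-biased pathways for systematic validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
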