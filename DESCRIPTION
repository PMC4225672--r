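Package: trntopo
Title: Topology, Modules, and Motifs of Transcriptional Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the topological analysis of bacterial transcriptional
    regulatory networks (TRNs) given as regulator-to-target edge lists with
    regulator class (transcription factor or sigma factor), regulatory mode,
    and evidence-strength annotations. Computes in-/out-degree distributions,
    clustering coefficients, and complementary cumulative degree distributions
    with least-squares power-law versus exponential tail fits; detects
    regulatory modules among regulators by hierarchical average-linkage
    clustering of the inverse-squared shortest-path association function, with
    Girvan-Newman community detection as an alternative and chance-corrected
    partition comparison; enumerates feed-forward and complex feed-forward
    three-node motifs, assesses their over-representation against a
    degree-preserving edge-switching null model, classifies master and local
    regulators, and quantifies intra- versus inter-module motif embedding.
    Includes a seeded synthetic-network generator with planted modules, motifs,
    a housekeeping hub, and power-law out-degree for end-to-end validation, and
    a one-call pipeline producing a machine-readable analysis report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
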