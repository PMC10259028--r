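Package: grnevo
Title: Coupled Sequence and Gene Regulatory Network Evolution Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward-time simulation of multi-gene coding sequences that
    coevolve with the gene regulatory network they encode. Organisms carry a
    genome plus an interaction matrix, activation thresholds and decay rates;
    a discrete-time dynamical system develops gene-expression profiles, a
    genetic algorithm with truncation or relaxed selection evolves
    populations along a user-defined phylogeny whose branch lengths are
    generation counts, and every synonymous or nonsynonymous point mutation
    triggers exactly one regulatory-parameter mutation in the affected gene.
    Includes fitness scoring of expression profiles, Jukes-Cantor distance
    utilities for neutral calibration, per-gene FASTA export across lineages,
    and plotting of fitness and participation traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    ggplot2,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
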