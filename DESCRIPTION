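Package: hetnet
Title: Topology, Hubs and Dense Modules in GPCR Heteroreceptor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing undirected receptor-receptor interaction
    networks such as the G protein-coupled receptor (GPCR) heteroreceptor
    network. Reads and normalises edge tables (TSV/CSV/SIF) into simple
    undirected graphs with family annotations, computes degree and
    clustering-coefficient distributions, shortest-path statistics, density
    and relative connectivity, classifies networks as random, scale-free or
    hierarchical from competing linear and power-law fits, identifies hubs
    under four alternative criteria including the successive-subgraph
    relative-connectivity procedure, detects dense modules with an MCODE-style
    vertex-weighting and seeded-expansion algorithm, and generates seeded
    synthetic networks (Erdos-Renyi, preferential attachment, hierarchical,
    and graphs matching published GPCR heteromer summary constraints) for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
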