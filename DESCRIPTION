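Package: regmetnet
Title: Integrated Regulatory-Metabolic Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing integrated gene-regulatory and
    metabolic networks of the kind reconstructed for Escherichia coli from
    BioCyc-style databases. Provides a typed annotated-graph data model with
    GraphML input/output, a reduced-fidelity parser and network assembler for
    BioCyc attribute-value flat files, functional and vertex-driven domain
    partitions into metabolic domain, protein interface and regulatory domain
    (MD-PI-RD), partition-aware topology metrics (modularity, inter-module
    edge fraction, embeddedness, betweenness, hub detection), enumeration of
    domain-traversing paths and regulatory-metabolic feedback loops, and a
    synthetic network generator with planted domain labels for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
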