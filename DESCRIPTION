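Package: gcmkit
Title: Gene-Context Based Metabolic Module Definition and Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Defines biologically relevant sub-pathway modules inside
    metabolic pathway networks and detects their presence on bacterial
    genomes by the juxtaposed (operon-like) occurrence of the constituent
    genes' protein domains, rather than by homology alone. Parses KGML
    pathway files into compound/reaction graphs, partitions them into
    edge-connectivity communities (initial reference modules), builds
    ordered genome catalogs of genes and their Pfam domains from PTT
    protein tables and HMMER3 domain tables, refines modules by clustering
    genes on genomic proximity, validates modules with a six-query
    literature consensus filter, and scans genomes with a sliding
    gene-rank window for a configurable percentage of a module's domains.
    Ships a synthetic-fixture generator for fully offline testing and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
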