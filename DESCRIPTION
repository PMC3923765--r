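Package: bionetviz
Title: Hierarchical Biological Network Visualization, Omics Projection and
    Path Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for drawing and analysing metabolic and
    regulatory networks. Provides a hierarchical network model with
    collapsible groups, reaction hyperedges, entity aliasing and layered
    visual properties; readers and writers for SIF, KGML, an SBML core
    subset, tabular omics data, identifier-mapping tables, GraphML and a
    versioned JSON project format; a generic framework for projecting
    omics values onto visual attributes including time-series glyphs and
    compartment-ambiguity colouring; force-directed, compartment-layered
    (Sugiyama) and KEGG fixed-position layout engines; a three-step
    incremental rendering pipeline emitting publication-quality SVG; and
    configurable graph flattening with k-shortest-path and breadth-first
    analyses whose results are projected back onto the drawing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
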