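Package: bdmlr
Title: Read, Write, Validate and Analyse Biological Dynamics Markup Language (BDML 0.2) Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete toolkit for the Biological Dynamics Markup Language
    (BDML, version 0.2), an XML format for quantitative spatiotemporal
    dynamics of biological objects ranging from single molecules to cells to
    whole organisms. Provides an in-memory document model with
    invariant-enforcing constructors, a lossless XML reader/writer backed by
    a shipped XML Schema, semantic validation with machine-readable
    violation reports and a one-fault injection harness, pixel-to-physical
    scale and unit conversion, geometric summaries over the five spatial
    entity types (point, line, circle, sphere, face), lineage-graph
    reconstruction from backward component links (tracks, divisions,
    fusions, per-track feature time series, Newick export), seeded synthetic
    data generators covering five canonical data shapes, and a command-line
    interface for validation, inspection, CSV conversion, generation and
    time-series splitting.
License: MIT
Encoding: UTF-8
Imports:
    xml2,
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, ape, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
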