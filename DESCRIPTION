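Package: provtrace
Title: Lightweight Provenance Capture for Data Analysis Scripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Captures fine-grained data provenance while an analysis script
    runs. Data-processing functions are wrapped so that each call records its
    inputs, outputs, parameters, object metadata (attributes and annotations),
    container-access relationships, and execution order. The captured history
    is serialized as an RDF graph following the W3C PROV-O ontology with an
    extension vocabulary for function executions, parameters, and object
    metadata, using deterministic URN identifiers so that records from
    independent runs merge into a single connected lineage graph. Serialized
    provenance can be projected onto property graphs for inspection,
    simplified by membership condensation and null-output removal, summarized
    with SNAP-style attribute/edge aggregation, and exported to GEXF or
    GraphML for graph-visualization tools. Includes a synthetic multichannel
    electrophysiology demo pipeline (trial cutting, filtering, downsampling,
    Welch spectral estimation) exercising the full capture stack.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    uuid,
    igraph,
    xml2,
    signal,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
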