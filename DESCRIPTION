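Package: hicdomains
Title: Probabilistic Topological Domain Segmentation and
    Promoter-Enhancer Interaction Calling from Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments single-chromosome Hi-C contact maps into
    topologically associating domains (TADs) with a per-distance
    two-component log-Normal mixture model and an exact dynamic
    programming optimizer, merges adjacent domains into hierarchical
    structures with a profile-regression merge score, fits each domain,
    merge region and the inter-domain background ("Sky") with a
    bi-linear (two-segment) power-law distance-decay model, and calls
    statistically over-represented promoter-anchored interactions
    (putative enhancers) from the residual map with Benjamini-Hochberg
    FDR control. Includes a synthetic Hi-C generator with known domain
    structure, decay parameters and planted enriched interactions, plus
    readers and writers for dense/sparse matrix text, BED, BEDPE and
    TSV annotation formats.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
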