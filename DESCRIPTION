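Package: dormclass
Title: Transcriptome Classification of Dormant and After-Ripened Seed Compartments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing dormant (D) and after-ripened (AR)
    seed transcriptomes over an imbibition time course on dissected seed
    compartments (micropylar/chalazal endosperm and radicle). Implements
    noise-clipped fold-change differential-expression calling with a t-test,
    dual-threshold expressed/specific gene calling, a two-step temporal
    classification of regulated genes into five classes, decomposition of
    differential expression into underlying temporal profiles, dual
    state-and-compartment enrichment sets, hypergeometric overrepresentation
    analysis against GMT catalogs, and PCA sample ordination. Ships a
    synthetic-data generator emulating the 2-state x 2-compartment x 5-time
    design with planted gene classes and per-gene truth labels, so every stage
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
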