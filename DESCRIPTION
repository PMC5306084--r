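Package: stoptox
Title: Transcriptome-Based Developmental Toxicity Indices for Stem Cell
    Test Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores chemically disturbed stem-cell differentiation from
    normalized expression matrices. Calls developmental (D) and toxicant
    (T) gene sets by differential expression, computes the developmental
    potency (Dp = O/D) and developmental index (Di = (O/T)/(D/N)) with
    hypergeometric overlap significance, quantifies antagonism between
    compound effects and spontaneous development, identifies toxicant-class
    consensus and diagnostic genes, builds a CLR transcription-factor
    co-expression network from k-nearest-neighbour mutual information with
    community detection and regulation overlay, and derives benchmark
    concentrations (BMC10) from viability dose-response curves. Includes
    seeded synthetic-data generators with planted truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    sva,
    igraph,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
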