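Package: aqpscan
Title: Genome-Wide Aquaporin Family Annotation and Comparative Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide characterization of the plant
    aquaporin (major intrinsic protein, MIP) gene family: gene-inventory
    curation and gene-model arithmetic, structure-anchored extraction of the
    dual NPA motifs, the aromatic/arginine (ar/R) selectivity filter, Froger's
    positions and nine specificity-determining positions (SDPs), rule-based
    substrate prediction from degenerate SDP profiles, subfamily and subgroup
    classification by pairwise similarity with neighbor-joining tree support,
    duplicate-pair typing and ancestral family-size bookkeeping, and FPKM
    expression summarization. A seeded synthetic-data generator produces
    AQP-like protein families, gene models and tissue count tables with known
    planted truth, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
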