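Package: boundscan
Title: Protein Domain Boundary Prediction from Evolutionary Signals in
    Query-Anchored Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects putative protein domain boundary sites from terminal-gap
    signals in multiple sequence alignments anchored on a query sequence, and
    classifies those sites with a two-stage support vector machine over a
    sliding-window encoding of sequence profiles, predicted secondary
    structure, solvent accessibility and positional features. Includes
    precision/recall evaluation against domain definitions with a tunable
    decision threshold, protein-level single- versus multi-domain calling,
    and a synthetic protein-family simulator with planted fusion/fission
    architectures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
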