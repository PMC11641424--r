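Package: rassemble
Title: Conformational Ensembles from Randomized Alanine Scanning and Shallow MSA Subsampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates and characterizes protein conformational ensembles by
    perturbing the inputs of an AlphaFold2-style structure predictor: randomized
    alanine sequence scanning of the query combined with shallow subsampling of
    the multiple sequence alignment. Provides a pluggable predictor backend
    (including a deterministic two-basin mock for desk-scale testing), Kabsch
    superposition and TM-score metrics against apo and holo reference
    structures, pLDDT-based confidence reranking, apo/holo state classification,
    and Ward-linkage hierarchical clustering with silhouette model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    cluster,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
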