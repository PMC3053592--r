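Package: chromex
Title: Chromatin Contact and Gene Co-Expression Analysis
Version: 0.1.0
Authors@R: person("chromex", "maintainers", email = "chromex@example.org",
    role = c("aut", "cre"))
Description: Genome-scale analysis of whether spatial proximity of genes,
    measured by chromosome-conformation-capture (Hi-C) contact matrices,
    associates with gene co-expression after controlling for shared
    transcription-factor regulation. Implements observed/expected contact
    normalization and its Pearson-correlation derivative, weighted bin-level
    gene-pair interaction, transcription control similarity, normalized
    genomic distance, cross-cell-type interaction rank matching, equal-size
    binned correlation testing with Bonferroni correction, Wang-method GO
    semantic similarity with best-match-average gene scores, and a fully
    seeded synthetic-data generator (distance-decay contacts, compartment
    blocks, coupled expression, sparse TF network, toy GO DAG) so that the
    whole pipeline is testable without external datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
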