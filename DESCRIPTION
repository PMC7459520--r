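Package: regmaster
Title: Master Regulator Inference from Co-Expressed Gene Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reverse engineering of transcriptional master regulators from a
    list of co-expressed genes. Implements rank-and-recovery cis-regulatory
    enrichment (recovery curves, top-fraction AUC, normalized enrichment
    scores, leading-edge target prediction), similarity clustering of enriched
    motifs with confidence-based transcription factor assignment, regulatory
    network construction with centrality analysis and tertile-based hub
    selection, protein-protein interaction expansion with hypergeometric
    kinase enrichment, and hypergeometric overlap of hub-centered
    transcriptional clusters with pathway gene sets (GMT). A synthetic-data
    generator with planted regulons, hub-structured interactomes, and planted
    pathway sets provides ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
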