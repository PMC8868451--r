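Package: meatID
Title: Meat Species Identification and Contamination Calling from 16S
    rRNA Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for DNA-barcoding authentication of
    meat products using the mitochondrial 16S rRNA gene. Generates
    synthetic multi-genus mitochondrial reference panels, performs
    in-silico PCR with degenerate universal primers, simulates paired-end
    2x300 amplicon reads from species mixtures, applies adapter, quality
    and length filtering, assigns reads to references by k-mer seeded
    local alignment, quantifies per-genus composition as percentage
    average fold coverage, calls contamination and mislabelling against
    a 98 percent purity threshold, and reproduces the validation
    statistics (chi-square proportion tests, contingency tests with
    Cramer's V) of a meat-authentication survey.
License: MIT
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
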