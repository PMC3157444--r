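Package: mycnet
Title: Integrative Reconstruction of a c-Myc Regulatory Network from
    miRNA and mRNA Profiling
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs a two-arm c-Myc regulatory network from paired
    miRNA qPCR-array and mRNA microarray profiling of a knockdown versus
    wild-type comparison. Provides TaqMan low-density-array CT
    preprocessing (censoring at 35 cycles, U6 delta-CT normalization,
    detection filtering, per-cell copy-number estimation), two-group
    fold-change/ANOVA differential filtering with probe-to-gene
    collapsing, seed-match miRNA target prediction at two stringencies
    intersected with anti-correlated expression, MATCH-style position
    weight matrix scanning of promoter regions with core/matrix
    similarity scores and empirically calibrated thresholds,
    hypergeometric gene-set over-representation analysis, and assembly
    of the transcriptional (promoter motif) and post-transcriptional
    (miRNA target) regulatory arms and their overlap. A synthetic-study
    generator with known planted truth makes every stage testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
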