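Package: mycomplete
Title: Marker-Based Completeness Assessment of Fungal Genome Assemblies and Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assesses how complete a fungal genome assembly or long-read set is
    by searching it for a curated set of conserved protein marker families and
    highly conserved non-coding DNA elements. Marker families are summarised as
    position-specific scoring matrices with per-family detection thresholds
    (80% of the weakest member's self-score); assemblies are scanned by
    six-frame translation, seeded ungapped extension with X-drop termination,
    and colinear HSP chaining into gene models classified as complete, partial
    or aberrant. Multi-copy families with fewer copies than expected flag
    potentially collapsed assembly regions. Unassembled long reads are assessed
    by reservoir-sampled blocks with a rarefaction stopping rule. A synthetic
    data generator (marker families, genomes with known embedded loci,
    truncated assemblies, simulated long reads) provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
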