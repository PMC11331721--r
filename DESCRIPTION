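Package: markerprof
Title: Marker-Gene Taxonomic Profiling of Long Metagenomic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates total prokaryotic genome copies and species-level
    taxonomic (cell-fraction) abundance profiles from long metagenomic reads
    using universal single-copy ribosomal protein marker genes. Marker-gene
    coverage is summarised with a positional trimmed mean and averaged over an
    eight-gene marker set to obtain genome copies; ambiguous nucleotide
    alignments of marker-containing reads are resolved with an
    expectation-maximisation reassignment followed by hard assignment.
    Includes the marker-screening statistics (universality, deviance,
    F0.5-score, circular genomic distances with single-linkage clustering),
    extraction of marker-gene-containing windows for reference database
    construction, profile evaluation metrics (genome-copy recovery,
    precision/recall/F1, four abundance dissimilarities, hierarchical
    genome-size correction), an antibiotic-resistance-gene copies-per-cell
    layer, and a synthetic community/alignment generator with known ground
    truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
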