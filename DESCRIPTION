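Package: paraldiv
Title: Protein-Family Profile Surveys and Conserved-Site Paralog Divergence Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale pipeline for genome-wide transcription-factor family
    surveys and for detecting recent functional divergence between gene-duplicate
    paralogs. Builds position-specific log-odds profiles from seed alignments,
    calibrates E-values against shuffled-sequence nulls, scans proteomes for
    domain occurrences with completeness and one-protein-per-locus filtering,
    screens a catalog of secondary sequence motifs, classifies family members
    into subfamilies with neighbor-joining trees, bootstrap supports and labeled
    anchor sequences, and scans an ortholog reference alignment for positions
    where one paralog of a duplicated pair departs from a deeply conserved
    residue, mapping alignment columns to per-sequence residue numbering and
    annotating domain context. Includes a seeded synthetic-data generator that
    plants domains, motifs and divergent sites with recorded ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
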