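Package: dwdmine
Title: Discovery, Classification and Phylogenetics of DDB1-Binding WD40
    (DWD) Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide discovery and characterization of DDB1-binding
    WD40 (DWD) proteins, the substrate receptors of CUL4-RING E3
    ubiquitin ligases.  Detects WD40 repeat proteins with a
    WD-anchor chaining heuristic or from precomputed domain
    annotations, scans them for the conserved 16-residue DWD motif,
    classifies domain architectures into generic types, characterizes
    hits against a reference DWD database by pairwise global alignment
    percent similarity, builds neighbor-joining trees of motif
    sequences with p-distances and bootstrap supports, cuts trees into
    groups, and computes per-species summary statistics.  Includes a
    seeded simulator of multi-species proteomes with planted WD40
    repeats, DWD motifs and homolog families evolved along a known
    species tree, so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
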