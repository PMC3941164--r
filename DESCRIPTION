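Package: methanodiv
Title: Clone-Library Diversity Analysis for Methanogen Marker Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for clone-library surveys of methanogen
    communities using paired marker genes (16S rRNA DNA sequences and
    deduced mcrA amino-acid sequences). Computes pairwise evolutionary
    distances from pre-aligned sequences, assigns operational taxonomic
    units (OTUs) by furthest-neighbor (complete-linkage) clustering at a
    percent-similarity cutoff, calibrates the protein-marker cutoff from
    paired 16S/mcrA distances by through-origin regression, derives
    per-library diversity statistics (Shannon-Wiener index, evenness,
    Good's coverage, Chao-1 richness), compares two libraries with the
    LIBSHUFF coverage-curve permutation test, and builds neighbor-joining
    trees with nonparametric bootstrap support. A synthetic-data module
    generates clone libraries with planted OTU structure so every stage is
    testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
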