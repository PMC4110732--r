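Package: mitoscan
Title: Evolution-Based Association Scanning of Mitochondrial Haplotype Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evolution-based association analysis of full mitochondrial
    genomes against a continuous phenotype such as relative mtDNA copy number.
    Extracts variants from pre-aligned mitochondrial genomes, collapses individuals
    into haplotypes with matrilineal imputation, builds a parsimony haplotype
    network as the union of all minimum spanning trees of the Hamming graph,
    enumerates loop resolutions and branch bipartitions, and tests every branch
    for phenotype association adjusted for age, sex and pedigree relatedness
    (via kinship coefficients and familial adjustment scores), using
    Freedman-Lane residual permutations, step-down minP/maxT family-wise
    correction and a conditional second scanning round for within-clade
    heterogeneity. Includes a synthetic cohort generator with a truth record so
    the full pipeline is testable without access to protected study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    igraph,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
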