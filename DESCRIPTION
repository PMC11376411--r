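Package: catforge
Title: Construction and Evaluation of Microbial Genome Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building dereplicated species-level catalogs of
    microbial genomes and evaluating taxonomic profilers against them.
    Implements genome quality gating (completeness/contamination tiers,
    chimerism score filtering), MinHash genome sketching and Mash-style
    distance estimation, fragment-based average nucleotide identity with
    aligned-coverage reporting, two-tier species clustering with
    conspecific dereplication and intactness-score representative
    selection, species-specific marker-gene selection by coreness and
    uniqueness with fragment-remapping refinement, genome-size-normalized
    abundance profiles with recall/precision/Bray-Curtis evaluation and
    centered log-ratio transforms, Fisher-exact enrichment statistics for
    between-catalog functional comparison, and a synthetic-data generator
    that plants species structure, pangenome architecture and community
    abundances so every component is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
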