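Package: aquadetect
Title: Coverage-Breadth Detection of Bacterial Species in Metagenomes
    and Genome-Based Species Demarcation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decides whether a bacterial species is present in a shotgun
    metagenome from read-mapping coverage: reads are placed on a
    concatenated, ribosomal-operon-masked reference at a 95% identity
    threshold, per-genome coverage breadth and depth are computed, and
    presence is called with an exponential breadth-threshold curve
    calibrated by stepwise read subsampling. Companion tools compute
    fragment-based average nucleotide identity, digital DNA-DNA
    hybridization estimates, 16S rRNA gene identity, distance-based
    phylogenies (Kimura two-parameter distances, neighbour joining,
    bootstrap support, midpoint rooting), core-gene selection from
    pan-genomes, and conserved-block alignment filtering. A synthetic
    community module simulates genomes, divergent relatives, shared
    ribosomal-like repeats, and labelled shotgun reads under a
    Lander-Waterman coverage model so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    phangorn,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
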