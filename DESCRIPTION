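Package: ithniche
Title: Spatial Intratumoural Heterogeneity and Niche Analysis for Tile-Grid
    Immunohistochemistry and Region-Stratified Mutational Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies intratumoural heterogeneity (ITH) from virtual
    1 mm2 tile grids laid over immunohistochemistry sections: per-square
    positive-nuclear-count and positive-pixel-count positivity with
    corrected-area normalisation, heterogeneity scores (s.d., MAX-mu),
    Shannon and inverse Simpson diversity indices over binned positivity,
    and a D'Agostino-Pearson omnibus classification of heterogeneous
    samples. Partitions tumour lattices into peripheral and central zones,
    tests peak-expression enrichment in the periphery with a Bernoulli
    trial, and correlates markers across aligned sections. A companion
    variant module stratifies central versus peripheral somatic variants,
    applies recurrence, dbSNP, functional-class and per-category
    strand-bias filters, classifies SNVs into the 96 trinucleotide
    categories, normalises by the target-region triplet background and
    compares spectra by cosine similarity. Includes synthetic generators
    for marker grids, slide-like label images and region-stratified
    variant sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
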