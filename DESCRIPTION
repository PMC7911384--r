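Package: paleomito
Title: Species Identification from Ancient Mitochondrial DNA Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying the species of origin of degraded
    (ancient) DNA samples from short sequencing reads, using competitive
    mapping against a panel of candidate mitochondrial genomes. Implements
    a desk-scale seed-and-verify read mapper with circular-genome support,
    an evenness-of-coverage statistic, cytosine-deamination damage
    profiling for authenticity assessment, threshold-based consensus
    calling, reference-anchored multiple alignment with diversity
    statistics, median-joining haplotype networks, and distance-based
    phylogenetic placement with bootstrap support. A fully seeded
    synthetic ancient-read generator makes the entire analysis testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    ape,
    igraph,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
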