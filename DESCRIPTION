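Package: kmerstruct
Title: Population Structure from Canonical k-mer Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free population structure inference from genome
    sequences. Counts canonical k-mers per sample, intersects profiles
    across samples after singleton filtering, and resolves population
    stratification with PCA followed by elbow-selected K-means clustering,
    scored against known labels with adjusted mutual information. Includes
    a forward-time multi-deme Wright-Fisher simulator emitting labeled
    FASTA genomes for validation, and a MinHash/Mash-distance
    neighbor-joining comparison workflow with monophyly testing over a
    (k, sketch size) parameter grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
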