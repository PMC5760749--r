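Package: genomepair
Title: Comparative Analysis of Closely Related Bacterial Genome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the pairwise comparative genomics of closely related
    bacterial strains: reciprocal (bidirectional) best-hit ortholog mapping
    with per-pair amino-acid identity, synteny profiling and detection of
    contiguous regions of gene-content difference, fragment-based average
    nucleotide identity (ANI), and a modal codon usage test for horizontal
    gene transfer with a shuffled gene-pool permutation null. Includes a
    synthetic annotated genome-pair simulator with truth records so every
    stage of the pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
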