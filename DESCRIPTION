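Package: petiteseq
Title: Structural Inference of Yeast Petite Mitochondrial Genomes from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the repeat structure of mitochondrial DNA
    in Saccharomyces cerevisiae Petite colonies from long-read alignment
    records. Detects and clusters alignment breakpoints, filters Nanopore
    inverted-duplication artifacts, reconstructs tandem and mixed concatemer
    repeat units, corrects structure frequencies for read-length sampling
    bias, classifies contingent excisions against the primary structure,
    simulates excision null models conditioned on replication origins, and
    fits a phenomenological model of suppressivity (the replicative fitness
    of Petite mtDNA against wild type). Includes a synthetic long-read
    alignment generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
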