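Package: retroburst
Title: Intra-Family Recombination Analysis for LTR Retrotransposon
    Transposition Bursts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying intra-family recombination
    during transposition bursts of LTR retrotransposon families from
    short-read sequencing. Implements member-specific read assignment via
    70-bp address sequences, exhaustive enumeration of inter-member
    recombination-junction fragment libraries, closed-form and permutation
    null models for sequencing-error artefacts, blunt-end read-pair
    detection of linear extrachromosomal DNA with parental classification,
    insertion calling from discordant pairs and junction reads with LTR
    reconstruction, parental haplotype painting of recombinant elements,
    and parental contribution scoring. A seeded synthetic-burst simulator
    generates families, recombinant ecDNA, integrated progeny genomes and
    paired-end reads with machine-readable ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
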