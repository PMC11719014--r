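Package: pseudoscan
Title: Pseudogene Screening, Gene-Loss Mapping and Oviduct Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens multi-species coding alignments for disabling mutations
    (start-codon loss, frameshift indels, premature stop codons) by projecting
    exon annotations of a functional reference into a codon coordinate system
    and walking each taxon's reading frame through its indels. Classifies taxa
    as intact, pseudogenized or indeterminate, maps gene-loss events onto a
    species tree by Dollo parsimony and phrases each loss relative to the
    sister lineage that diverged before it. Includes the two ancillary
    computations used in oviduct gene-expression studies: 2^-ddCt relative
    quantification of qPCR panels and exact peptide-to-protein span mapping,
    plus a synthetic-data generator that implants a catalogue of lesions into
    a simulated murine-style locus with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
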