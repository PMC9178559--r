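Package: xlfrag
Title: Fragmentation Analysis of MS-Cleavable Crosslinked Peptide Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fragmentation spectra of chemically
    crosslinked peptide pairs, with a focus on MS-cleavable crosslinkers
    (DSSO, DSBU) and their signature stub-fragment doublets. Provides
    in-silico tryptic digestion, theoretical fragment generation with
    cleaved-stub and intact-partner (+P) masses, ppm-tolerant spectrum
    annotation with deisotoping and intensity ranks, signature-doublet
    detection and rank statistics, conservative sequence-coverage metrics,
    MS3 trigger-correctness evaluation, grouped target-decoy FDR
    estimation with doublet prefiltering, and a ground-truthed synthetic
    spectrum generator emulating stepped-HCD and CID-MS2-MS3 acquisition.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
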