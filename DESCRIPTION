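Package: srnakit
Title: Small RNA-Seq Processing, Annotation and IsomiR Analysis for
    Incompletely Annotated Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for small RNA sequencing of species with
    incomplete miRNA annotation. Implements adapter clipping that retains
    only clipped reads, leading-N removal, read collapsing into unique
    sequence count tables, counts-per-million low-evidence filtering,
    exact-match cross-species annotation against prioritized miRNA, rRNA,
    tRNA, piRNA-cluster, mRNA and other ncRNA references with removal of
    miRNA candidates that also hit tRNA or rRNA, and characterization of
    isomiR end variants (templated and non-templated 5'/3' additions and
    deletions, canonical detection, within-miRNA expression ranking).
    Ships a fully ground-truthed synthetic small RNA library generator so
    every stage is testable without external data.
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
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
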