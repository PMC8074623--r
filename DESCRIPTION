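Package: ampliscope
Title: In-Silico Design and Evaluation of Universal Metabarcoding Primers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating universal metabarcoding
    primer pairs against taxonomically annotated reference sequence
    databases. Implements candidate primer enumeration under quorum and
    mismatch constraints, physico-chemical primer screening
    (nearest-neighbour melting temperature, GC content and clamp,
    homopolymer and dinucleotide repeats, self-complementarity),
    mismatch-tolerant in-silico PCR with degenerate (IUPAC) primers,
    taxon-level coverage and specificity indices with
    lowest-common-ancestor resolution of ambiguous amplicons,
    multi-marker complementarity (Venn) analysis, sliding-window
    nucleotide diversity profiles over multiple alignments, and a seeded
    synthetic reference-database generator with full ground truth for
    end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
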