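Package: hatannot
Title: Annotation, Classification and Phylogeny of Plant hAT DNA Transposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to annotate consensus hAT-superfamily DNA transposon
    sequences. Detects terminal inverted repeats (TIRs) anchored on a
    degenerate nucleotide motif with configurable mismatch budgets, derives a
    TIR consensus pattern from detected arms, discovers transposase open
    reading frames by six-frame translation, checks the five catalytic-residue
    activity signature against a reference transposase, classifies elements as
    autonomous or nonautonomous and links N-suffixed deletion derivatives to
    their parents, and builds neighbor-joining phylogenies with bootstrap
    support. A synthetic element generator with planted ground truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tibble,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
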