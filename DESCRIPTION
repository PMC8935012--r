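Package: pcfm
Title: Detection and Analysis of Compensatory Frameshifting Mutation Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects pairs of mutually compensatory frameshifting indels
    (pCFMs) in gapped alignments of orthologous protein-coding sequences on a
    species phylogeny, using parsimony placement of insertion/deletion events
    and a cascade of sequence-quality and length filters. Characterizes the
    position of detected pairs along the coding sequence, the conservation
    context of the genes and regions that carry them, and the effect of the
    frame shift on the encoded protein via Miyata amino-acid distances and
    Kyte-Doolittle hydropathy, with empirical null distributions built by
    in-silico frameshifting of control genes. Includes a closed-form
    mutation-selection-balance (stochastic tunneling) model for the expected
    number of genes carrying such pairs, and a sequence simulator with a known
    truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
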