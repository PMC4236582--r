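Package: scarless
Title: Design and In Silico Verification of Scarless Two-Step Genome-Editing Cassettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automates the design of mutation cassettes for scarless two-step
    genome editing in bacteria (lambda-Red integration followed by I-SceI
    counter-selection and RecA-mediated resolution). Supports point mutations,
    insertions, deletions and essential-gene edits with synonymous-codon
    recoding, terminator-shielded selection cassettes, Shine-Dalgarno
    consensus scoring and silent ribosome-binding-site boosting, a
    quantitative crossover-position model of integration outcomes, in silico
    execution of the integration/cleavage/resolution steps, Gibson-style
    assembly planning and amplification-primer design, and GenBank/FASTA/TSV/
    JSON input and output. A deterministic synthetic-genome fixture generator
    is included for testing and examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
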