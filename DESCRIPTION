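Package: chlorocargo
Title: Screening for Chloroplast Vesicle-Transport Cargo Proteins and Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a bioinformatic screen for putative
    cargo proteins, cargo receptors and fusion components of a COPII-like
    vesicle transport system inside chloroplasts. Provides a Prosite-style
    sorting-signal pattern engine (diacidic, dihydrophobic, di/mono-basic, ILV
    and dilysine motifs), membrane-topology region maps with positional and
    orientation filters, a multi-tool subcellular-localization consensus
    decision tree, an affine-gap global aligner for detecting N-terminal
    transit-peptide extensions, and a synthetic-proteome generator with ground
    truth so that every stage of the screen is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
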