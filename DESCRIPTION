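Package: multipcr
Title: Multiplex Species-Diagnostic PCR Panel Design and In-Silico PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and evaluating multiplex PCR panels that
    identify mammalian species from mitochondrial cytochrome b (cytb)
    markers, as used to authenticate the host species of field-collected
    faecal samples. Provides an IUPAC-degenerate, mismatch-tolerant virtual
    PCR engine for linear and circular templates; conservation and
    discrimination profiling of per-species alignments; degenerate primer
    candidate enumeration with Wallace and nearest-neighbor melting
    temperature estimates and 3'-anchored cross-dimer scoring; size-spaced
    panel selection with specificity validation; virtual agarose-gel band
    interpretation and survey-level morphology-versus-molecular
    reconciliation; and a seeded generator of species-structured synthetic
    genomes and faecal surveys for end-to-end testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
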