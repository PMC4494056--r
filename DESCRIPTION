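Package: hsreg
Title: Identification of Human-Specific Transposable-Element-Derived
    Regulatory Loci
Version: 0.1.0
Authors@R:
    person("hsreg", "maintainers", email = "hsreg@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for identifying candidate
    human-specific transcription-factor-binding loci derived from
    transposable elements and characterizing them by repeat association,
    nuclear-lamina and methylation-domain colocalization, proximity
    placement enrichment near gene sets, deamination-driven k-mer
    evolution, 5-hydroxymethylcytosine strand patterning, individual- and
    archaic-genome conservation, and an evolutionary creation-rate model.
    Includes a synthetic multi-species cohort generator with known ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
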