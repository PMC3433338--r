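Package: pyromut
Title: Pyrogram Simulation and Hotspot Mutation Calling for
    EGFR, KRAS and BRAF Pyrosequencing Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models pyrosequencing signal generation for targeted
    hotspot assays and analyses measured pyrograms. Simulates expected
    peak patterns for wildtype/mutant template mixtures over an assay's
    dispensation order, filters non-specific peaks with an
    unexpected-position noise cutoff, recognises which catalogued
    mutation (if any) a pyrogram contains by least-squares mixture
    deconvolution, quantifies the mutant percentage, and reports
    per-peak wildtype/mutant attribution with a configurable calling
    threshold. Ships built-in assay definitions for EGFR (codons 719,
    746-753, 768, 790, 858), KRAS (codons 12, 13, 61) and BRAF (codon
    600), a JSON catalog format for user-defined assays, a seeded
    synthetic-pyrogram generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
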