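Package: selotools
Title: Comparative Genomics of C-Terminal Cys/Sec Motifs and the SELO Protein Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative-genomics characterisation of
    selenoprotein O (SELO/ydiU/FMP40)-like protein families: anchored
    PROSITE-style C-terminal motif matching and census of CxxC/CxxU redox
    motifs, exact log-space binomial overrepresentation tests stable far
    into the extreme tail, greedy redundancy reduction of homologue sets at
    a percent-identity threshold, rescue of selenocysteine residues
    misannotated as stop codons from coding sequences, genomic-neighbourhood
    COG enrichment around focal genes, and microbial lifestyle (trait)
    enrichment.  Includes seeded synthetic-data generators that emulate the
    statistical structure of each input so every analysis stage can be
    validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
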