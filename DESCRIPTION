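Package: orgHGT
Title: Detection of Horizontally Transferred Plastid Sequences in Plant
    Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("orgHGT", "Developers", email = "orghgt@example.org",
           role = c("aut", "cre"))
Description: Tools to detect plastid-derived sequences in plant
    mitochondrial genomes (MTPTs), classify them as native
    (intracellular transfer) or foreign (horizontal transfer) by
    phylogenetic incongruence with bootstrap support, and weigh
    mitochondrion-to-mitochondrion transfer evidence from the 1 kb
    regions flanking each foreign MTPT.  Includes a reverse-direction
    detector for mitochondrion-derived sequences in plastid genomes
    (PTMTs), a desk-scale seed-and-extend nucleotide local aligner
    producing BLAST-tabular-compatible hits, and a seeded organellar
    genome simulator that implants intracellular and horizontal
    transfer events with a ground-truth log, so every pipeline stage
    is verifiable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
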