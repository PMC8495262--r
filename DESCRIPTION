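Package: srnase
Title: Characterization and Molecular Evolution of S-RNase Allele Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing self-incompatibility ribonuclease
    (S-RNase) allele families from partial amplicon sequences spanning the
    second (C2) to the fifth (C5) conserved region of rosaceous S-RNases.
    Annotates exon/intron structure and conserved protein regions, calls
    loss-of-function mutations (frameshifts, premature stop codons, splice
    acceptor defects), sizes amplicons into gel bands at limited resolution,
    computes three-level pairwise identity matrices (exon nucleotide,
    deduced amino acid, second intron), classifies trans-specific allele
    pairs, profiles conservative versus non-conservative amino acid
    replacements by structural region, and builds distance-based
    neighbor-joining trees with bootstrap support. Includes a seeded
    synthetic allele-family generator with a complete truth table so every
    stage can be tested without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
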