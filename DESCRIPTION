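Package: psychrossb
Title: Characterization Statistics for Psychrophilic Single-Stranded
    DNA-Binding Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytical layer for the biochemical characterization of
    bacterial single-stranded DNA-binding proteins (SSBs) from
    cold-adapted bacteria: sequence-derived physicochemical statistics
    (monomer mass, isoelectric point, aliphatic index), amino-acid
    composition cold-adaptation indices, identity/similarity scoring of
    pairwise alignments under a six-group residue similarity scheme,
    oligomeric-state inference from gel-filtration calibration curves,
    ssDNA binding-site-size estimation from inverse fluorescence
    titrations, duplex-melting destabilization, and thermal-inactivation
    half-lives, together with seeded synthetic-data generators emulating
    the instrument outputs so every analysis stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
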