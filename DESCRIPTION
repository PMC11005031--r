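Package: circrecomb
Title: Repeat-Mediated Recombination Analysis for Circular Organelle Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects dispersed direct and inverted repeats on circular
    genomes such as plant mitogenomes, enumerates the isomeric genome
    forms generated by homologous recombination between repeat copies
    (flip-flop inversion at inverted repeats, fission and fusion at
    direct repeats), builds flank+repeat+flank junction references for
    every repeat pair, and classifies long reads into reference versus
    alternative configurations to quantify per-pair rearrangement rates.
    Includes read-curation filters (organelle read extraction by query
    coverage, duplex-like artifact removal, full-length linear read
    accounting) and a planted-truth simulator of circular genomes and
    isomer-mixture long-read sets so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
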