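Package: memtopo
Title: Topology Census of the Human Membrane Proteome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing curated topology tables of ER-inserted
    alpha-helical membrane proteins. From per-protein transmembrane-domain
    (TMD) coordinates and orientation, the package deduces loops and tails
    with alternating membrane sidedness, scores TMDs with a
    position-dependent biological hydrophobicity scale (apparent free energy
    of membrane insertion, dG_app), classifies proteins into single-pass
    Type I-IV and multipass topology classes, detects TMD pairs, assigns
    each TMD one of six core membrane-insertion reactions, computes
    positive-inside-rule flanking charge statistics and five-zone
    intramembrane charge maps, and aggregates everything into a census
    report. A synthetic-proteome generator with full truth bookkeeping
    makes the entire pipeline testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
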