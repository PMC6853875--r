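Package: spies3d
Title: 3D Scattered Pair Interaction Energies for Fragment Molecular
    Orbital Interface Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Residue-based fragmentation of protein complexes for two-body
    fragment molecular orbital (FMO) calculations, generation of GAMESS-style
    FMO input decks, and parsing of pair interaction energy decomposition
    analysis (PIEDA) tables.  Implements the 3D-SPIEs screen: pair
    interaction energies are filtered by single-linkage inter-fragment
    distance and an attractive-energy threshold to identify inter-protein
    contacts, intra-protein stabilising interactions, and water-bridge
    interactions, with hot-spot region grouping and interaction maps
    aggregated across complexes.  Includes deterministic synthetic fixtures
    (toy multi-chain structures and synthetic PIEDA output) so the whole
    pipeline is testable without quantum-chemistry runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
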