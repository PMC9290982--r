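Package: helixweak
Title: Weak Spots in Transmembrane Helices of G Protein-Coupled Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies weakened backbone hydrogen bonds ("weak
    spots") in the transmembrane helices of G protein-coupled receptors and
    other helical membrane proteins.  Provides backbone hydrogen-bond
    energetics with amide-hydrogen placement, annotation of pi-bulge and
    3-10 helix irregularities, attribution of each weak spot to a causal
    residue mechanism (proline, glycine flexibility, side-chain clamping,
    inter-helix contacts), GPCRdb-style generic residue numbering anchored
    at x50 positions, grid-based cavity and escape-channel detection for
    the cytosolic sodium exit below position 2x46, leucine gate rotamer
    analysis, pentamer fragment searches for rotamer distributions, and
    cross-structure conservation profiling of weak-spot locations.  A
    deterministic synthetic-structure generator builds ideal and distorted
    helices, seven-helix bundle phantoms with planted weak spots, channel
    phantoms of known geometry, and fragment databases, so every stage of
    the analysis can be validated against constructed ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
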