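Package: chimeragraft
Title: Loop Grafting Between Structurally Related Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs loop-grafted chimeric proteins between two structurally
    related input structures. Provides secondary-structure assignment with
    user overrides, extraction of loops (SSE-coil-SSE super-secondary
    structures) and their geometry (distance and hoist, packing and meridian
    angles), per-residue flexibility from crystallographic B-factors, NMR
    ensembles and Gaussian/anisotropic elastic network models, residue and
    segment cross-correlation analysis, rigid-body superposition with greedy
    alpha-carbon residue pairing, exhaustive enumeration of recombination
    boundaries yielding a deduplicated chimeric sequence library, and
    preparation of multi-template modelling inputs (trimmed templates,
    locally superposed fragments, PIR alignments) with score-based ranking
    of externally evaluated models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    seqinr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
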