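Package: PairSpace
Title: Scale-Free Analysis of Amino Acid Pair Interactions in Protein Structures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds an 8-dimensional sparse count tensor of amino-acid pair
    interactions from protein structure coordinates and per-residue
    annotations (secondary structure and relative solvent accessibility).
    Pairs are detected between side-chain functional atoms within the same
    solvent-accessibility shell, binned by residue types, accessibility,
    spatial distance, secondary structures, chain length and sequence
    separation. Provides a composition-preserving within-chain shuffling
    null model with observed/expected cell ratios, rank-frequency tables
    with log2-log2 power-law fits over arbitrary dimension subsets, and
    descriptive summaries of highly populated cells (pair matrices,
    accessibility-by-distance histograms, secondary-structure and
    per-residue rank profiles). Includes a synthetic corpus generator so
    the full pipeline can be exercised and validated without external
    structure databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'PairSpace-package.R'
    'binScheme.R'
    'utils.R'
    'pairs.R'
    'structureIO.R'
    'synthetic.R'
    'scalefree.R'
    'summaries.R'
    'randomization.R'
    'tensorIO.R'
    'cli.R'
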