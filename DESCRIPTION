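Package: AlloHDX
Title: Mapping Orthosteric and Allosteric Ligand Responses from HDX-MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing peptide-level amide hydrogen/deuterium
    exchange mass spectrometry (HDX-MS) experiments on protein-ligand
    systems. Implements a two-state kinetic model of exchange at
    ligand-occluded amides, experimental-design arithmetic (dilutions,
    ligand:protein ratios, fractional occupancy, saturation checks),
    relative deuterium uptake and reporter-region identification,
    apo-versus-bound difference profiles with a fixed Dalton significance
    threshold, merging of significant peptides into residue-interval
    response regions, overlay of a ligand-bound structure to classify
    regions as orthosteric or allosteric by a distance-cutoff contact
    rule, and ranking of ligands and fragments by the number and
    magnitude of the responses they elicit. A seeded simulator generates
    synthetic exchange time courses and structures for validation,
    including a fixture encoding the Hsp90 N-terminal domain ligand
    response catalogue.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    bio3d,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AlloHDX-package.R'
    'accessors.R'
    'structure.R'
    'uptake.R'
    'regions.R'
    'classify.R'
    'kinetics.R'
    'simulate.R'
    'fixture.R'
    'io.R'
    'pipeline.R'
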