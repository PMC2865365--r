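Package: xtalsym
Title: Detection of Underassigned Rotational Symmetry in Macromolecular
    Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to decide whether a deposited protein crystal structure is
    nearly invariant under additional rotational symmetry operators of a
    higher-symmetry space group. Starting from a PDB coordinate model (and
    optionally merged reflection intensities), the package removes lattice
    centring, reduces the unit cell, searches the lattice metric for
    candidate twofold axes (Le Page delta angles), enumerates and scores
    candidate Patterson settings with the symmetry-operator reliability
    statistic R_symop, positions the model in each candidate space group by
    an intensity-correlation translation search, discriminates rotation from
    screw operators with an amplitude-weighted phase-agreement score,
    matches symmetry-equivalent chains through a left coset decomposition,
    refines the origin shift by exact least squares, quantifies the
    deviation from perfect symmetry (RMS C-alpha displacement and its
    rigid-body/residual split) and writes reduced asymmetric-unit models for
    re-refinement. Exact rational space-group algebra for all 65 Sohncke
    groups is included, together with a seeded generator of synthetic
    underassigned-symmetry crystals for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'symop.R'
    'changebasis.R'
    'cell.R'
    'spacegroup.R'
    'model.R'
    'structurefactors.R'
    'io.R'
    'kearsley.R'
    'lepage.R'
    'translation.R'
    'matching.R'
    'patterson.R'
    'rsymop.R'
    'reduce.R'
    'pipeline.R'
    'rational.R'
    'synthetic.R'
    'xtalsym-package.R'
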