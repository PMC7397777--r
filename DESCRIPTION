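Package: pHLAdock
Title: Structural Modeling of Peptide-HLA Complexes by Incremental
    Docking and Anchored Ensemble Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling the bound geometry of short peptides (8-11
    residues) in the groove of class I HLA receptors.  Provides a full-atom
    peptide data model with torsion-tree kinematics, empirical Vina-class
    pairwise scoring functions, a parallel incremental meta-docking algorithm
    that reconstructs a flexible peptide fragment by fragment in the binding
    site, an anchored ensemble generator that samples bound backbones by
    randomized coordinate-descent loop closure between groove anchor pockets,
    and end-to-end workflows for geometry prediction, ensemble-based binding
    energy estimation, and two-stage (sequence prefilter + structural
    re-ranking) virtual screening of candidate peptides.  A synthetic fixture
    generator builds toy receptor pockets with planted ground-truth binding
    modes and labeled binder/decoy screening sets so that every algorithm can
    be exercised without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    yaml,
    jsonlite,
    pROC,
    parallel
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'topology.R'
    'geometry.R'
    'AllClasses.R'
    'AllGenerics.R'
    'scoring.R'
    'runtime.R'
    'docking.R'
    'ensemble-gen.R'
    'fixtures.R'
    'peptide.R'
    'pdb-io.R'
    'workflows.R'
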