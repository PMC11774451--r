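Package: cfmdock
Title: Conditional Flow-Matching Docking of Flexible Protein-Ligand Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative protein-ligand docking by conditional flow matching
    from an unbound (apo) protein and a harmonic bond-graph ligand prior to the
    bound (holo) complex. Provides the harmonic Gaussian ligand prior built from
    the bond-graph Laplacian, apo-to-holo pair curation with weighted Kabsch
    alignment, TM-score and RMSD acceptance filters, a CondOT conditional path
    and flow-matching regression loss, a compact rotation-equivariant radial
    network with confidence (plDDT-style) and binding-affinity heads, a
    variance-diminishing ODE sampler for ranked pose generation, and a
    deterministic synthetic toy-complex generator for training and testing at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    ChemmineR,
    ChemmineOB,
    Biostrings,
    igraph,
    MASS,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'config.R'
    'chem-smiles.R'
    'chem-pdb.R'
    'priors.R'
    'coupling.R'
    'network.R'
    'flow.R'
    'sampler.R'
    'synthetic.R'
    'cli.R'
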