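Package: drugspace
Title: Physicochemical Property and Conformer-Ensemble Shape Analysis of
    Oral Drug Space
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for profiling the physicochemical property space of
    small-molecule oral drugs. Computes rule-of-5 descriptors (molecular
    weight, calculated logP, hydrogen-bond donor and acceptor counts) plus
    flexibility and shape proxies (rotatable bonds, aromatic rings,
    fraction of sp3 carbons, stereocentres), classifies compounds by
    Lipinski compliance, macrocyclic character and ionisation state,
    derives percentile-based property rules from a dataset, and compares
    subsets with Tukey-Kramer HSD tests. A deterministic conformer-ensemble
    pipeline (OpenBabel embedding, systematic torsion search, MMFF94
    optimisation) feeds principal-moments-of-inertia shape descriptors
    that are Boltzmann-averaged over the ensemble at 300 K. A
    fragment-grammar generator produces synthetic compound libraries with
    planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    ChemmineR,
    ChemmineOB,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: OpenBabel 3 (obabel and obenergy on the PATH)
biocViews: Cheminformatics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'obmol.R'
    'descriptors2d.R'
    'classify.R'
    'conformer3d.R'
    'dataset-io.R'
    'drugspace-package.R'
    'shape3d.R'
    'stats.R'
    'synthetic.R'
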