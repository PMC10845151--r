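Package: deltaBH
Title: Delta-Machine-Learning Correction of Semiempirical Reaction Barrier Heights
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts high-level (DFT-quality) reaction barrier heights from
    cheap semiempirical (PM7-style) calculations by learning the correction
    BH_DFT - BH_PM7. Provides molecular-graph construction from 3D geometries,
    eigenvalue fingerprints for connectivity and conformation screening of
    IRC-connected reaction records, custom reaction descriptors (topological
    indices of the transition-state graph, formed/broken bond counts,
    semiempirical electronic descriptors including Koopmans hardness and
    electronegativity), standard cheminformatics delta-descriptors, Pearson
    correlation feature pruning, three regression heads (gradient-boosted
    trees, exact Gaussian-process regression with a Matern-5/2 kernel, and a
    multitask neural network), SHAP-based interpretability, rigid-rotor
    harmonic-oscillator thermochemistry for Gibbs energies of activation, and
    a seeded synthetic reaction generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    xgboost,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
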