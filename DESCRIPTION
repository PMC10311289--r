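Package: pocketmolgen
Title: Pocket-Conditioned Controllable Molecule Generation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A controllable, protein-pocket-oriented molecule generator.
    Binding pockets are represented as paired residue-level and atom-level
    spatial K-nearest-neighbour graphs with Gaussian radial-basis edge
    embeddings and Laplacian-eigenvector positional features, encoded by an
    edge-augmented multi-head attention transformer with one-way
    residue-from-atom cross-view fusion.  A property-conditioned
    autoregressive transformer decoder over a sub-token SMILES vocabulary
    generates molecules under explicit binding-affinity and drug-likeness
    conditions.  Includes synthetic pocket and corpus generators, training
    with validation-driven learning-rate decay and early stopping, top-k
    sampling, and evaluation metrics (validity, Tanimoto diversity,
    high-affinity ratio, property compliance) backed by RDKit descriptors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with RDKit, used via the command line
    for molecular descriptors and fingerprints.
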