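Package: PRIcontact
Title: Max-Margin Prediction of Residue-Base Contact Maps in
    Protein-RNA Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts residue-base contact maps between a protein and an
    RNA from sequence and predicted secondary structure alone.  A sparse
    linear scoring model over k-mer and structural-profile features is
    decoded by exact integer programming under consistency constraints
    (binding-site indicators, no isolated bound bases, per-residue and
    per-base contact caps), and trained with a structured support vector
    machine using loss-augmented inference, AdaGrad step sizes and l1
    regularization.  Includes contact-map extraction from 3D coordinates
    by a heavy-atom distance criterion, a fully synthetic corpus
    generator with planted weights, three-level evaluation metrics
    (contact, binding residue, binding base), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    bio3d,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
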