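Package: pepcascade
Title: Cascaded Machine-Learning Prediction of MHC-I Binding Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting binding of octapeptides to the murine
    MHC class I allomorph H-2Kb with a cascaded (stacked-generalization)
    machine-learning model. Provides six peptide sequence descriptors
    (amino-acid frequencies, binary identity and pharmacophore-type
    encodings, a topological pharmacophore pair descriptor, and
    property-scale principal-component encodings with an auto-correlated
    length-invariant variant), a two-stage ensemble of neural-network and
    support-vector-machine base classifiers combined by an exhaustively
    selected jury network ranked by Matthews correlation coefficient,
    wildcard fragment-library enumeration for dissecting reference
    epitopes, sliding-window proteome scanning, and a thermal-shift assay
    analyzer that extracts melting points from fluorescence curves and
    summarizes replicate binding panels. Includes seeded synthetic-data
    generators (motif-structured peptide sets and two-state melting
    curves) so the full pipeline is reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nnet,
    e1071,
    seqinr,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
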