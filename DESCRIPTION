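Package: ppiscore
Title: Scoring and Assessment of Rigid-Body Docked Protein-Protein Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for generating, featurizing, and assessing rigid-body docked
    models of protein heterodimers. Computes the DockQ model-quality metric and its
    components (Fnat, ligand RMSD, interface RMSD), solvent-accessibility based
    interface residue detection, physical interface features (heavy-atom contact
    count and SVM interface separability), the DockQ-weighted landscape anisotropy,
    DockQ-uniform subsampling and class balancing of decoy ensembles, correlation,
    classification and hit-rate evaluation statistics, a two-feature support vector
    regression scoring function, and linear bound-to-unbound conformational
    interpolation of monomers. Includes synthetic structure and score-table
    generators so the whole pipeline can be exercised at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    e1071,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
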