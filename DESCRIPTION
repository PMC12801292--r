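Package: PharmScreen
Title: Consensus Pharmacological-Interaction Scoring for Structure-Based
    Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-docking rescoring of virtual-screening hits with
    pharmacological interaction fingerprints. Detects and types
    protein-ligand contacts (hydrogen bonds; alkyl, pi-stacking and mixed
    hydrophobic contacts) in docked poses, derives per-structure sets of
    key interactions from their frequency among top-ranked known actives,
    scores compounds by combining interaction matches with the docking
    score, and aggregates per-structure rankings into a consensus ranking
    across a receptor ensemble. Includes a drug-likeness filter cascade
    (HTS, Lipinski, Veber, PAINS, QED), redocking RMSD validation with
    symmetry correction, ROC-AUC enrichment evaluation against decoys,
    ECFP/Tanimoto similarity analysis with leader clustering, and a fully
    synthetic benchmark generator with planted interaction signals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'PharmScreen-package.R'
    'chem-io.R'
    'interactions.R'
    'pharm-model.R'
    'scoring.R'
    'evaluate.R'
    'qed-data.R'
    'filters.R'
    'fixtures.R'
    'similarity.R'
    'pipeline.R'
    'utils.R'
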