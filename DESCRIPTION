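Package: idpscreen
Title: Ensemble Fragment Mapping and Docking Screens for Intrinsically
    Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Structure-based small-molecule discovery for intrinsically
    disordered proteins represented as conformational ensembles.  Reads
    multi-model PDB ensembles, characterizes conformers by radius of
    gyration, solvent accessible surface area and non-bonded contact
    count, selects a diverse compactness-biased subset, maps fragment
    probes over conformer surfaces to locate druggable hot spots scored
    by per-heavy-atom ligand efficiency, assembles proximal hot spots
    into binding pockets, and runs a rigid-receptor flexible-ligand
    docking screen of fragment-like compound libraries ranked by
    within-pocket energy rank and ligand efficiency.  Includes a
    synthetic disordered-ensemble generator with plantable surface
    cavities so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    PATH (used for SMILES/SDF parsing, partial charges and 3D conformer
    generation)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
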