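Package: pblocks
Title: Protein-Block Local Structure Assignment and Sequence-Based Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for describing protein backbone local structure with the
    16-letter protein-block (PB) structural alphabet and for predicting it from
    amino-acid sequence alone.  Builds PB prototype backbones from dihedral
    angles with fixed peptide geometry, computes RMSDA (angular) and
    Kabsch-superposed RMSD (Cartesian) distances, and represents each
    five-residue fragment by its "structural coordinates" (the 16-vector of
    RMSDs to the PB prototypes).  Provides the full sequence-to-structure
    pipeline: physicochemical and occurrence-statistics feature generation,
    stepwise F-statistic feature selection with correlation deduplication, a
    shallow multi-output regression network trained with Adam, and Q3/Q8/Q16
    evaluation with confusion matrices and RMSD-profile correlations.  Includes
    a synthetic backbone generator so every stage is testable without external
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
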