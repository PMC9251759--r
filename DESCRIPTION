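Package: phosphoFLR
Title: Decoy Amino Acid Estimation of the False Localization Rate in
    Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of the global false localization rate (FLR) for
    phosphosite reporting from search-engine site tables. Implements the
    decoy amino acid method, in which localization is additionally scored
    on a residue that cannot be phosphorylated so that every hit on it is
    a known false localization, together with a model-based estimator
    built on summed local error probabilities and an answer-key estimator
    for synthetic peptide libraries. Includes target-decoy PSM FDR
    filtering, site expansion with combined probabilities, q-value
    monotonization and thresholding, collapsing of multi-PSM site
    observations, histogram-based score calibration, de Bruijn (k = 2)
    decoy protein database generation, decoy-suitability profiling
    diagnostics, and a ground-truth simulator of site-level search output
    for validating the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'phosphoFLR-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'psmFdr.R'
    'sites.R'
    'estimators.R'
    'calibration.R'
    'collapse.R'
    'utils.R'
    'decoyDatabase.R'
    'profiling.R'
    'simulate.R'
    'pipeline.R'
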