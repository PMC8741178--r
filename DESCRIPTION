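Package: coronaRF
Title: Sequence-Based Prediction of the Protein Corona on ssDNA-SWCNT Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts which proteins adsorb into the protein corona of
    single-stranded-DNA-functionalized single-walled carbon nanotube
    (ssDNA-SWCNT) nanoparticles from amino-acid sequence alone. Derives
    physicochemical and solvent-exposure descriptors from protein sequences,
    labels proteins as in or out of the corona from quantitative LC-MS/MS
    abundance tables via an enrichment rule combined with an
    exponential-decay abundance threshold, trains an imbalance-corrected
    (SMOTE) random-forest classifier with stratified shuffle-split
    validation, ranks features by univariate ANOVA F statistics, and
    predicts in-corona probabilities for novel proteins. Includes a
    synthetic-data generator that emulates the statistical structure of the
    corona proteomics inputs so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
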