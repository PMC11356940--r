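Package: fpscreen
Title: Evaluation of Fingerprint-Based Virtual Screening with Decoy
    Retention Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how well molecular-fingerprint
    similarity separates active compounds from decoys in ligand-based
    virtual screening. Implements the decoy retention factor (DRF), an
    early-enrichment statistic that measures the decoy load remaining
    above the score threshold recovering a chosen fraction of actives,
    alongside ROC AUC, BEDROC, cutoff-survival fractions and cumulative
    recovery curves. Provides a native LINGO (SMILES q-gram) fingerprint,
    Tanimoto similarity with bit-vector folding, ingestion of externally
    computed fingerprints, a per-target screening pipeline with
    aggregation across protein targets, Kendall rank correlation of
    similarity against compound potency (AC50), arithmetic for
    extrapolating decoy counts to billion-molecule libraries, and a
    synthetic benchmark generator with known ground truth for calibration
    and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'extrapolation.R'
    'fingerprint.R'
    'fpscreen-package.R'
    'io.R'
    'metrics.R'
    'pipeline.R'
    'potency.R'
    'synthetic.R'
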