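Package: pmcmeta
Title: Literature Mining and Coordinate-Based Meta-Analysis for PubMed
    Central Full Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for bulk retrieval and parsing of PubMed Central
    full-text XML (JATS), extraction of stereotactic brain coordinates
    from article tables in both the XHTML and OASIS table dialects,
    grammar-based extraction of participant counts and demographics from
    running text, TF-IDF featurization of article corpora, voxelwise
    chi-square coordinate-based meta-analysis with false-discovery-rate
    control, and a ridge model predicting brain maps from text features.
    Includes exporters for text-annotation (JSONLines) and
    coordinate-dataset (JSON) interchange formats, a resumable batched
    download client with a pluggable transport, a synthetic JATS corpus
    generator with a full ground-truth ledger for offline testing, and a
    step-cached command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    xml2,
    jsonlite,
    Matrix,
    RNifti,
    stringi
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'transport.R'
    'pmcClient.R'
    'jats.R'
    'tables.R'
    'coords.R'
    'tfidf.R'
    'meta.R'
    'demographics.R'
    'annotations.R'
    'synthetic.R'
    'pipeline.R'
    'zzz.R'
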