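Package: qamskit
Title: Single-Marker Quantification and Fingerprint Chemometrics for HPLC
    Quality Evaluation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quality evaluation of herbal material from HPLC-DAD data:
    chromatogram input/output, baseline correction, peak detection and
    trapezoidal integration; external-standard calibration and quantitative
    analysis of multi-components by a single marker (QAMS) with relative
    correction factors and method-agreement statistics; chromatographic
    fingerprint similarity against a reference profile; chemometric batch
    evaluation with hierarchical clustering, Kaiser-Meyer-Olkin and Bartlett
    sphericity adequacy tests, principal-component factor analysis with
    varimax rotation and a variance-weighted composite quality score; and
    range analysis of L9(3^4) orthogonal extraction designs. Includes a
    synthetic chromatogram generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
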