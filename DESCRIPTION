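Package: qamsfp
Title: Chromatographic Fingerprints and Single-Marker Quantitation for
    Herbal Preparations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quality evaluation of multi-herb liquid preparations from
    UPLC chromatograms: peak detection and integration with baseline and
    noise estimation, alignment of common peaks across batches by relative
    retention time, vector-cosine fingerprint similarity with non-common
    peak area statistics and log2 clustering heatmaps, external-standard
    calibration (linearity, LOD/LOQ at 3:1 and 10:1 signal-to-noise), and
    quantitative analysis of multi-components by a single marker (QAMS)
    through relative correction factors, with relative-error agreement
    checks against the external standard method. Includes a seeded
    synthetic chromatogram generator with full ground truth, accurate-mass
    feature annotation, and the published validation tables of a
    seven-compound assay of an eleven-herb preparation as reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
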