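Package: qamsHPLC
Title: Single-Marker Quantification (QAMS) for HPLC-DAD Assays of 5-HT3
    Receptor Antagonists
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative analysis of multi-components by a
    single marker (QAMS) on liquid-chromatography diode-array-detector
    data, developed around a five-analyte assay of the setron class of
    antiemetics (ondansetron, azasetron, granisetron, tropisetron,
    ramosetron) with ondansetron as the internal reference. Provides a
    seeded LC-DAD run simulator with known ground truth, chromatographic
    peak detection and integration, per-analyte linear calibration with
    LOD/LOQ, relative correction factors and single-marker
    quantification, qualitative identification by dead-time-corrected
    relative retention time and UV spectral cosine similarity (raw and
    first-derivative), and ICH-style validation campaigns (precision,
    stability, recovery, robustness), together with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    signal,
    pracma,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
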