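Package: difc
Title: Two-Color Diffuse In Vivo Flow Cytometry Signal Processing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal processing for two-color diffuse in vivo flow cytometry
    (DiFC): moving-median background subtraction, noise-adaptive transient
    peak detection, cross-probe directional peak matching, two-fluorophore
    (2-lambda) coincidence classification via a spectral bleed-through
    threshold, amplitude-based cluster sizing, and scan-level detection-rate
    and correlation analysis. Includes a synthetic scan simulator with known
    ground truth (Poisson cell arrivals, log-normal per-cell brightness,
    spectral bleed, drifting background, motion artifacts) so that every
    pipeline stage can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
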