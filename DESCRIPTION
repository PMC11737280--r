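Package: ccimatch
Title: Cross-Correlation Matching of MALDI-TOF Mass Spectra for
    Mosquito Species Identification
Version: 0.1.0
Authors@R:
    person("ccimatch", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An open data-analysis pipeline for identifying Anopheles
    mosquito species from MALDI-TOF protein mass spectra. Implements
    spectral preprocessing (square-root transform, Savitzky-Golay
    smoothing, SNIP baseline removal, total-ion-current normalization,
    rigid-shift alignment), a cross-correlation index (CCI) computed as
    the product of local maxima of the normalized cross-correlation
    function over fixed mass intervals, reference-database construction
    and querying with identification thresholds and technical
    replicates, and a simulation-based evaluation of identification
    performance (sensitivity, specificity, predictive values, accuracy
    with equal-tailed credible intervals). A seeded synthetic-spectrum
    generator with species-, specimen- and spot-level variability makes
    the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
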