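Package: eroxtract
Title: Objective Extraction of Evoked Event-Related Oscillations from ERP Data
Version: 0.1.0
Authors@R: person("ERO", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for extracting evoked event-related oscillations (EROs)
    from multi-subject event-related potential (ERP) recordings. Implements
    temporal principal component analysis with Promax rotation and
    back-projection of selected components to the electrode fields, complex
    Morlet wavelet time-frequency representations with baseline power
    subtraction, and objective delineation of oscillation regions on
    time-frequency images with a Canny edge detector. Includes a synthetic
    ERP generator with known sources, latency/amplitude jitter and
    controlled signal-to-noise ratio, the conventional rectangle
    region-of-interest method and the TFA-PCA comparator, and validation
    statistics (Pearson recovery metrics, two-way repeated-measures ANOVA
    with Greenhouse-Geisser correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
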