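Package: thzwater
Title: Terahertz Spectral Chemometrics for Leaf Water Content
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for estimating leaf water content from
    terahertz time-domain spectra. Holds power, absorbance and transmittance
    channels on a common 0.5-1.5 THz frequency grid in a
    SummarizedExperiment-derived container, smooths spectra with
    Savitzky-Golay filtering, partitions samples into calibration and
    prediction sets with the Kennard-Stone and SPXY algorithms, selects
    moisture-informative frequency bands by stability competitive adaptive
    re-weighted sampling (SCARS), fits per-channel multiple linear regression
    models, and fuses the three channels through z-score normalization,
    principal component reduction at a cumulative-variance threshold and
    RBF-kernel epsilon support-vector regression. Includes a synthetic-data
    generator emulating irrigation-stress experiments so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
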