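Package: uptakemech
Title: Substrate-Rigidity-Dependent Particle Uptake: Mechanics Model and
    Quantification Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Thermodynamic model of phagocytosis-like uptake of micron-scale
    particles by adherent cancer cells as a function of substrate rigidity,
    together with the quantification steps the analysis rests on: Young's
    modulus estimation from gel-cube compression traces, threshold-based cell
    spreading area from two-channel fluorescence images, gating and uptake
    fractions from imaging-flow-cytometry event tables, a bootstrap test for
    non-monotonic ("meandering") rigidity dependence, and binomial
    maximum-likelihood fitting of the mechanics model to uptake curves. A
    synthetic-data generator emulates all wet-lab inputs so every stage is
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
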