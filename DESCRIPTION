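Package: oscrheo
Title: Non-Invasive Rheology of Pulsatile Epithelial Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers effective mechanical properties of epithelial cells from
    tracked-cell fluorescence time series. Apical-area and medial-myosin signals
    are turned into dimensionless strain and rescaled myosin, decomposed into
    time-resolved frequency components, and fed through a contractile linear
    viscoelastic (active Maxwell) constitutive model to obtain effective
    stiffness and loss tangent over developmental time. Includes hysteretic
    damping scale-factor fitting for relative stress estimates, strain-myosin
    hysteresis loops, Morlet wavelet coherence with a resampling null,
    neighbour myosin-phase analysis, hierarchical bootstrap confidence
    intervals, and a synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
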