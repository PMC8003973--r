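Package: canespec
Title: Chemometric Calibration of Sugarcane Quality from Vis-NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A reusable chemometric pipeline for predicting sugarcane quality
    parameters (Brix, Pol, Fibre, Pol of cane and total recoverable sugars)
    from visible/near-infrared spectra of four mill sample-preparation types.
    Implements standard normal variate and Savitzky-Golay second-derivative
    preprocessing with Pareto scaling, Kennard-Stone calibration-set
    selection, NIPALS partial least squares regression with venetian-blinds
    cross-validation and randomization-based latent-variable selection,
    Hotelling T2/Q and residual-based outlier loops, variable importance in
    projection (VIP) profiling, and a distribution-free randomization test
    for comparing prediction accuracy between sample types. A synthetic
    spectra generator with a Beer-Lambert band model makes the whole pipeline
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    tibble
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
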