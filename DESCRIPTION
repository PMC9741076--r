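Package: milkfatir
Title: Fatty Acid Profiling of Human Milk Fat from ATR-FTIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric calibration pipeline that predicts relative fatty acid
    concentrations (g/100 g fat) and their sum parameters in separated human milk
    fat from attenuated total reflection Fourier-transform infrared (ATR-FTIR)
    spectra. Implements Savitzky-Golay second-derivative preprocessing, NIPALS
    PLS1 regression, selectivity-ratio wavenumber-region selection via target
    projection, contiguous-blocks cross-validation with parsimonious latent
    variable selection, external validation figures of merit, PCA concordance of
    measured versus predicted profiles, and downstream clinical analyses
    (lactation-day trends, Holder pasteurization comparison, covariate screens).
    Includes a synthetic milk-fat spectra generator so the full chain is testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
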