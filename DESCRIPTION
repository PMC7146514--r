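Package: somspectra
Title: Soil Organic Matter Prediction from Vis-NIR Spectra via Optimal
    Band-Combination Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for predicting soil organic matter (SOM,
    g/kg) from visible/near-infrared (350-2500 nm) reflectance spectra.
    Implements spectral preprocessing (wavelength trimming, Gaussian-filter
    downsampling, Savitzky-Golay smoothing, continuum removal), PCA-based
    feature extraction, exhaustive two-band and three-band optimal
    spectral-index search against Pearson correlation with top-1% candidate
    retention and minimum calibration/validation correlation-error selection,
    rank-ordered 2:1 dataset splitting, linear and random-forest regression
    with out-of-bag mtry tuning, and R2/RMSE/RPIQ model evaluation with A-D
    RPIQ categories. Includes a synthetic soil-spectra generator that
    reproduces the statistical structure of a 168-sample arid-region soil
    survey (right-skewed SOM, SOM-driven visible darkening, water/clay
    absorption features) with planted SOM-linked bands for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    ggplot2,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
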