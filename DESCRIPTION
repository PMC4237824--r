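Package: dcerepro
Title: Scan-Rescan Reproducibility Analysis for Dynamic Contrast-Enhanced
    Vessel Wall MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and statistical analysis of scan-rescan
    reproducibility for quantitative dynamic contrast-enhanced (DCE) MRI of
    the carotid vessel wall. Provides a forward simulator for spoiled
    gradient echo DCE series of a vessel-wall phantom with Patlak kinetics,
    pixel-wise estimation of the transfer constant (Ktrans) and fractional
    plasma volume (vp) with registration, temporal smoothing and arterial
    input function extraction, variance-component reproducibility statistics
    (between-scan SD, coefficient of variation, intra-class correlation)
    with nonparametric bootstrap confidence intervals and permutation tests,
    Bland-Altman agreement analysis, and coefficient-of-variation based
    sample-size planning for two-arm longitudinal studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    RNifti,
    png
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
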