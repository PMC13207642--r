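Package: zrasim
Title: Simulation and Detection-Power Analysis for Implantable
    Zero-Resistance Ammetry Corrosion Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital twin of an implantable zero-resistance ammetry (ZRA)
    corrosion sensor for biodegradable magnesium implants in a mouse.
    Generates synthetic in vivo current records by combining electrochemical
    noise (Stern-Geary baseline, 1/f^2 pitting noise, hydrogen-bubble shot
    noise), bioelectric interference from a nine-ellipsoid anatomical phantom
    (cardiac current dipole, electromyographic bursts), and instrumental
    limitations (amplifier noise, Johnson-Nyquist noise, ADC resampling and
    quantization), all filtered through equivalent-circuit loop impedances
    including a two-zone coating-breach model. Provides the four detection
    metrics, Welch spectral estimation, sensitivity regression, and the
    Monte-Carlo detection-power framework that predicts the minimum
    statistically detectable coating breach for a given electrode design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
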