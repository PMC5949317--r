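Package: kmnir
Title: Particle-Size-Aware Kubelka-Munk Modelling of NIR Diffuse Reflectance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric toolkit for quantitative near-infrared (NIR) diffuse
    reflectance analysis of powders where particle size matters. Implements the
    Kubelka-Munk remission function and its inverses, sliding-window profiling
    of the linear region of apparent absorbance versus the absorption-to-scatter
    ratio k/s, scatter-correction preprocessing (MSC, EMSC, SNV, Savitzky-Golay
    smoothing and derivatives, normalization, baseline subtraction),
    Kennard-Stone calibration/validation splitting, NIPALS partial least squares
    with PRESS-based latent-variable selection, RPD-based model comparison
    across single and pooled sieve fractions, and a physics-based synthetic
    spectra generator for end-to-end testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
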