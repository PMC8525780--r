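Package: spectraphys
Title: Photosynthetic Trait Estimation from Gas Exchange and Leaf Reflectance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage pipeline for leaf photosynthetic trait estimation in
    diverse (tropical) canopies. Stage one fits the Farquhar-von
    Caemmerer-Berry (FvCB) model of net CO2 assimilation to A-Ci curves by
    maximum likelihood, with peaked-Arrhenius temperature normalization to
    25 degrees C, Wald uncertainty intervals, AIC-based selection of the
    triose-phosphate-utilization limb, and dark-respiration processing.
    Stage two trains ensemble partial least-squares regression (PLSR) models
    that predict Vcmax25, Jmax25, Tp25 and Rdark25 from leaf reflectance
    spectra (500-2400 nm), with resampled-PRESS one-standard-error component
    selection, confidence and prediction intervals, VIP scores, coefficient
    summaries, and random/species/site validation split designs. A synthetic
    data generator emulates the joint trait-spectra structure so the whole
    pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
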