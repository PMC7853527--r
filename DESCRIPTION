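Package: phiec
Title: Electron Requirement for Carbon Fixation from Fast Repetition Rate
    Fluorometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from fast repetition rate fluorometry (FRRf)
    observables and bottle-incubation productivity measurements to the
    electron requirement for carbon fixation (Phi_e,C) and daily gross
    primary productivity of lake phytoplankton. Includes FRRf quality
    control and photophysiology, layered diffuse-attenuation fitting,
    spectral underwater irradiance and spectral correction factors,
    oxygen- and 13C-based incubation rates, photosynthesis-irradiance
    curve fitting with photoinhibition, stratified bootstrap and gamma
    GLM all-subsets AIC model selection for Phi_e,C, depth-integrated
    daily productivity, and a synthetic campaign generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
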