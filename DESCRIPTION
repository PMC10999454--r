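Package: fingerppg
Title: Monte Carlo Simulation of Finger Photoplethysmography Across Skin
    Pigmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates red (660 nm) and infrared (940 nm) photon transport
    through a multi-layered human finger model at three epidermal melanin
    concentrations, in transmittance and reflectance photoplethysmography
    (PPG) geometries. The Monte Carlo engine implements weighted photon
    packets with implicit capture, Henyey-Greenstein scattering, Fresnel
    boundaries and Russian roulette over a slab stack with an embedded bone
    cylinder. Paired systole/diastole runs yield the pulsatile (AC) and
    baseline (DC) PPG components, AC/DC ratios, convergence diagnostics,
    per-layer absorbance, mean optical pathlength, mean penetration depth
    and photon propagation profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
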