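# Small-scale fixtures shared across the suite. Photon counts here trade
# statistical resolution for runtime; the acceptance tests run at study
# scale.

quick_scenario <- function(wavelength = 940, skin_type = "light",
                           phase = "diastole", mode = "transmittance",
                           sds = NULL, n_photons = 2e4, seed = 42L, ...) {
  scenario(wavelength, skin_type, phase, mode,
           sds = sds, n_photons = n_photons, seed = seed, ...)
}

# uniform deviates decoupled from the engine's own stream
unit_deviates <- function(n, seed) {
  withr::with_seed(seed, stats::runif(n))
}

table2_cells <- function() {
  tibble::tribble(
    ~tissue,            ~wavelength, ~mua,    ~mus,  ~g,
    "fat",                      660, 0.0104,  6.20,  0.90,
    "fat",                      940, 0.0170,  5.42,  0.90,
    "muscle",                   660, 0.0816,  8.61,  0.88,
    "muscle",                   940, 0.0401,  5.81,  0.91,
    "bone",                     660, 0.0351,  34.45, 0.92,
    "bone",                     940, 0.0457,  24.70, 0.93,
    "oxyhaemoglobin",           660, 0.15,    NA,    NA,
    "oxyhaemoglobin",           940, 0.65,    NA,    NA,
    "deoxyhaemoglobin",         660, 1.64,    NA,    NA,
    "deoxyhaemoglobin",         940, 0.43,    NA,    NA,
    "water",                    660, 0.00036, NA,    NA,
    "water",                    940, 0.02674, NA,    NA,
    "melanin",                  660, 26.94,   NA,    NA,
    "melanin",                  940, 8.299,   NA,    NA,
    "skin",                     660, NA,      25.62, 0.91,
    "skin",                     940, NA,      15.68, 0.94
  )
}

# total attenuation of the stratum corneum under the default composition
sc_mu_t <- function(wavelength) {
  sc <- skin_sublayers()[1, ]
  mua <- sc$v_water * water_mua(wavelength) +
    (1 - sc$v_water) * baseline_mua(wavelength)
  mus <- tissue_properties(wavelength)
  mua + mus$mus[mus$tissue == "skin"]
}
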