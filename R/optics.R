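#' Optical properties of the finger tissue components
#'
#' Literature absorption coefficient (`mua`, mm^-1), scattering coefficient
#' (`mus`, mm^-1) and scattering anisotropy (`g`) for every tissue component
#' of the finger model at the two pulse-oximetry wavelengths, 660 nm (red)
#' and 940 nm (infrared). Skin absorption is not tabulated because it is
#' computed per sublayer from chromophore composition and cardiac phase (see
#' [epidermis_mua()] and [dermal_mua()]); its scattering columns apply to all
#' six skin sublayers.
#'
#' @param wavelength Optional wavelength filter in nm (660 or 940).
#' @return A tibble with columns `tissue`, `wavelength`, `mua`, `mus`, `g`.
#' @export
#' @examples
#' tissue_properties(660)
tissue_properties <- function(wavelength = NULL) {
  tbl <- tibble::tribble(
    ~tissue,            ~wavelength, ~mua,     ~mus,   ~g,
    "skin",                     660, NA_real_, 25.62,  0.91,
    "skin",                     940, NA_real_, 15.68,  0.94,
    "fat",                      660, 0.0104,   6.20,   0.90,
    "fat",                      940, 0.0170,   5.42,   0.90,
    "muscle",                   660, 0.0816,   8.61,   0.88,
    "muscle",                   940, 0.0401,   5.81,   0.91,
    "bone",                     660, 0.0351,   34.45,  0.92,
    "bone",                     940, 0.0457,   24.70,  0.93,
    "oxyhaemoglobin",           660, 0.15,     NA_real_, NA_real_,
    "oxyhaemoglobin",           940, 0.65,     NA_real_, NA_real_,
    "deoxyhaemoglobin",         660, 1.64,     NA_real_, NA_real_,
    "deoxyhaemoglobin",         940, 0.43,     NA_real_, NA_real_,
    "water",                    660, 0.00036,  NA_real_, NA_real_,
    "water",                    940, 0.02674,  NA_real_, NA_real_,
    "melanin",                  660, 26.94,    NA_real_, NA_real_,
    "melanin",                  940, 8.299,    NA_real_, NA_real_
  )
  if (!is.null(wavelength)) {
    check_wavelength(wavelength)
    tbl <- dplyr::filter(tbl, .data$wavelength == !!wavelength)
  }
  tbl
}

#' Skin-pigmentation presets
#'
#' Melanosome volume fractions of the epidermis for the three simulated
#' pigmentation groups of the Fitzpatrick scale: light (types I-II, 2.55%),
#' moderate (IV-V, 15.5%) and dark (VI, 30.5%). Type III is not represented.
#'
#' @return A tibble with columns `skin_type` and `v_mel`.
#' @export
#' @examples
#' skin_presets()
skin_presets <- function() {
  tibble::tibble(
    skin_type = c("light", "moderate", "dark"),
    v_mel = c(0.0255, 0.155, 0.305)
  )
}

#' Skin sublayer composition table
#'
#' Default thickness, diastolic blood volume fraction and water volume
#' fraction of the six skin sublayers, surface inward. Thicknesses sum to the
#' model's total skin thickness of 0.95 mm. The stratum corneum and epidermis
#' are bloodless; epidermal absorption is driven by melanin instead (see
#' [epidermis_mua()]). During systole the dermal blood fractions are doubled.
#'
#' @return A tibble with columns `sublayer`, `thickness` (mm),
#'   `v_blood_diastole` and `v_water` (volume fractions).
#' @export
#' @examples
#' sum(skin_sublayers()$thickness)  # 0.95 mm
skin_sublayers <- function() {
  tibble::tribble(
    ~sublayer,          ~thickness, ~v_blood_diastole, ~v_water,
    "stratum_corneum",        0.02,              0.00,     0.05,
    "epidermis",              0.08,              0.00,     0.65,
    "papillary_dermis",       0.15,              0.04,     0.65,
    "upper_blood_net",        0.08,              0.30,     0.65,
    "reticular_dermis",       0.40,              0.04,     0.65,
    "deep_blood_net",         0.22,              0.10,     0.65
  )
}

check_wavelength <- function(wavelength) {
  if (!is.numeric(wavelength) || length(wavelength) != 1 ||
      !wavelength %in% c(660, 940)) {
    rlang::abort(
      "`wavelength` must be 660 or 940 (nm); no other optical data is tabulated.",
      class = "fingerppg_missing_property"
    )
  }
  invisible(wavelength)
}

lookup_property <- function(tissue, wavelength, column) {
  tbl <- tissue_properties()
  row <- tbl[tbl$tissue == tissue & tbl$wavelength == wavelength, ]
  row[[column]][[1]]
}

#' Melanin absorption coefficient
#'
#' Power-law absorption of epidermal melanin,
#' \eqn{\mu_a = 6.6 \times 10^{10} \, \lambda^{-3.33}} mm^-1 with
#' \eqn{\lambda} in nm: 26.94 mm^-1 at 660 nm and 8.299 mm^-1 at 940 nm.
#'
#' @param wavelength Wavelength in nm (any positive value).
#' @return Absorption coefficient in mm^-1.
#' @export
#' @examples
#' melanin_mua(c(660, 940))
melanin_mua <- function(wavelength) {
  if (!is.numeric(wavelength) || any(wavelength <= 0)) {
    rlang::abort("`wavelength` must be positive (nm)",
                 class = "fingerppg_invalid_parameter")
  }
  6.6e10 * wavelength^-3.33
}

#' Baseline (chromophore-free) skin absorption
#'
#' Background absorption of bloodless, melanin-free, dry skin tissue,
#' \eqn{(0.244 + 85.3 e^{-(\lambda - 154)/66.2})/10} mm^-1 (the classic
#' skin-optics baseline, tabulated in cm^-1 and converted here).
#'
#' @inheritParams melanin_mua
#' @return Absorption coefficient in mm^-1.
#' @export
baseline_mua <- function(wavelength) {
  if (!is.numeric(wavelength) || any(wavelength <= 0)) {
    rlang::abort("`wavelength` must be positive (nm)",
                 class = "fingerppg_invalid_parameter")
  }
  (0.244 + 85.3 * exp(-(wavelength - 154) / 66.2)) / 10
}

#' Water absorption coefficient
#'
#' @inheritParams melanin_mua
#' @return Absorption coefficient in mm^-1 at 660 or 940 nm.
#' @export
water_mua <- function(wavelength) {
  check_wavelength(wavelength)
  lookup_property("water", wavelength, "mua")
}

#' Epidermal absorption coefficient
#'
#' Volume-fraction-weighted chromophore sum for the epidermis:
#' \deqn{\mu_{a,epi} = v_{mel}\,\mu_{a,mel}(\lambda) + v_W\,\mu_{a,W}
#'   + (1 - v_{mel} - v_W)\,\mu_{a,base}(\lambda)}
#' with melanin from [melanin_mua()] and the residual volume filled by
#' baseline skin tissue ([baseline_mua()]). At the three pigmentation presets
#' this reproduces the model's epidermal coefficients: roughly 0.7, 4.2 and
#' 8.2 mm^-1 at 660 nm and 0.23, 1.3 and 2.5 mm^-1 at 940 nm for light,
#' moderate and dark skin.
#'
#' @param v_mel Melanosome volume fraction in \[0, 1\].
#' @param wavelength Wavelength in nm.
#' @param v_water Water volume fraction in \[0, 1\]; `v_mel + v_water` must
#'   not exceed 1. Default 0.65, the standard epidermal water content.
#' @param mua_water Water absorption in mm^-1; defaults to the tabulated
#'   value at `wavelength`.
#' @return Absorption coefficient in mm^-1.
#' @export
#' @examples
#' epidermis_mua(0.305, 660)  # dark epidermis, red light
epidermis_mua <- function(v_mel, wavelength, v_water = 0.65,
                          mua_water = water_mua(wavelength)) {
  if (any(v_mel < 0) || any(v_water < 0) || any(v_mel > 1) ||
      any(v_water > 1) || any(v_mel + v_water > 1)) {
    rlang::abort(
      "chromophore volume fractions must lie in [0, 1] and sum to at most 1",
      class = "fingerppg_invalid_parameter"
    )
  }
  v_mel * melanin_mua(wavelength) + v_water * mua_water +
    (1 - v_mel - v_water) * baseline_mua(wavelength)
}

#' Whole-blood absorption coefficient
#'
#' Saturation-weighted mixture of oxy- and deoxyhaemoglobin absorption,
#' \eqn{\mathrm{SpO_2}\,\mu_{a,HbO_2} + (1 - \mathrm{SpO_2})\,\mu_{a,Hb}}.
#' The finger model assumes fully oxygenated blood (`spo2 = 1`).
#'
#' @param wavelength Wavelength in nm (660 or 940).
#' @param spo2 Oxygen saturation as a fraction in \[0, 1\].
#' @return Absorption coefficient in mm^-1.
#' @export
#' @examples
#' blood_mua(660, 1)   # arterial blood, red light
blood_mua <- function(wavelength, spo2 = 1) {
  check_wavelength(wavelength)
  if (!is.numeric(spo2) || any(spo2 < 0) || any(spo2 > 1)) {
    rlang::abort("`spo2` must lie in [0, 1]",
                 class = "fingerppg_invalid_parameter")
  }
  spo2 * lookup_property("oxyhaemoglobin", wavelength, "mua") +
    (1 - spo2) * lookup_property("deoxyhaemoglobin", wavelength, "mua")
}

#' Dermal sublayer absorption coefficient
#'
#' Nested chromophore mixture for a vascularised dermal sublayer:
#' \deqn{\mu_a = v_b\,\mu_{a,blood} + (1 - v_b)\left[v_W\,\mu_{a,W}
#'   + (1 - v_W)\,\mu_{a,base}\right]}
#' where the blood volume fraction \eqn{v_b} equals the sublayer's diastolic
#' fraction during diastole and twice that during systole (the pulsatility
#' protocol: systolic dermal blood volume is doubled), and \eqn{v_W} is the
#' water fraction of the blood-free tissue matrix. Blood claims its volume
#' first, so the doubled systolic fraction of even the blood-rich upper
#' plexus stays a valid mixture.
#'
#' @param sublayer One row of [skin_sublayers()] (or a list with elements
#'   `sublayer`, `v_blood_diastole`, `v_water`).
#' @param phase `"systole"` or `"diastole"`.
#' @param wavelength Wavelength in nm (660 or 940).
#' @param spo2 Blood oxygen saturation, default 1.
#' @return Absorption coefficient in mm^-1.
#' @export
#' @examples
#' pap <- skin_sublayers()[3, ]
#' dermal_mua(pap, "systole", 660) > dermal_mua(pap, "diastole", 660)
dermal_mua <- function(sublayer, phase = c("diastole", "systole"),
                       wavelength, spo2 = 1) {
  phase <- rlang::arg_match(phase)
  check_wavelength(wavelength)
  name <- sublayer$sublayer
  if (name %in% c("stratum_corneum", "epidermis")) {
    rlang::abort(
      paste0("`", name, "` is avascular; dermal_mua() applies to the four ",
             "dermal sublayers only"),
      class = "fingerppg_invalid_parameter"
    )
  }
  v_b <- sublayer$v_blood_diastole * if (phase == "systole") 2 else 1
  v_w <- sublayer$v_water
  if (v_b > 1) {
    rlang::abort(
      "systolic blood doubling pushes the blood volume fraction above 1",
      class = "fingerppg_invalid_model"
    )
  }
  v_b * blood_mua(wavelength, spo2) +
    (1 - v_b) * (v_w * water_mua(wavelength) +
                   (1 - v_w) * baseline_mua(wavelength))
}

#' Export the resolved optical-property table
#'
#' Writes (or returns) the full property table as used by the simulation:
#' every tabulated tissue component plus the three resolved epidermis rows
#' (light/moderate/dark) at both wavelengths, with the refractive index
#' column carried by tissue regions.
#'
#' @param path Optional CSV destination; omit to just get the tibble.
#' @return A tibble with columns `tissue`, `wavelength_nm`, `mua_mm`,
#'   `mus_mm`, `g`, `n` (invisibly if written to `path`).
#' @export
export_property_table <- function(path = NULL) {
  base <- tissue_properties()
  skin_regions <- c("skin", "fat", "muscle", "bone")
  epi <- tidyr::expand_grid(skin_presets(), wavelength = c(660, 940))
  epi <- dplyr::mutate(
    epi,
    tissue = paste0("epidermis_", .data$skin_type),
    mua = purrr::map2_dbl(.data$v_mel, .data$wavelength, epidermis_mua),
    mus = purrr::map_dbl(.data$wavelength, lookup_property,
                         tissue = "skin", column = "mus"),
    g = purrr::map_dbl(.data$wavelength, lookup_property,
                       tissue = "skin", column = "g")
  )
  out <- dplyr::bind_rows(
    dplyr::mutate(base, n = ifelse(.data$tissue %in% skin_regions, 1.4,
                                   NA_real_)),
    dplyr::select(dplyr::mutate(epi, n = 1.4),
                  "tissue", "wavelength", "mua", "mus", "g", "n")
  )
  out <- dplyr::rename(out, wavelength_nm = "wavelength", mua_mm = "mua",
                       mus_mm = "mus")
  if (is.null(path)) return(out)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' First-step stratum corneum crossing probability
#'
#' Largest uniform deviate \eqn{\xi} for which the first sampled photon step
#' \eqn{-\ln(\xi)/\mu_t} surpasses a layer of thickness \eqn{d} at orthogonal
#' incidence, i.e. \eqn{e^{-\mu_t d}}. Used as a diagnostic of the stratum
#' corneum parameterisation: with the default composition the thresholds are
#' about 0.599 at 660 nm and 0.730 at 940 nm.
#'
#' @param mu_t Total attenuation coefficient of the layer in mm^-1.
#' @param d Layer thickness in mm.
#' @return Probability in (0, 1\].
#' @export
#' @examples
#' first_step_crossing_probability(25.65, 0.02)
first_step_crossing_probability <- function(mu_t, d) {
  stopifnot(mu_t > 0, d > 0)
  exp(-mu_t * d)
}
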