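#' Define a simulation scenario
#'
#' A scenario fixes everything one Monte Carlo run needs: wavelength, skin
#' pigmentation, cardiac phase, sensor geometry and the photon budget.
#' The experiment design spans \{light, moderate, dark\} x \{660, 940\} nm x
#' \{systole, diastole\} x \{transmittance, reflectance at source-detector
#' separations 1-9 mm in 2 mm steps\}.
#'
#' @param wavelength Wavelength in nm, 660 or 940.
#' @param skin_type `"light"`, `"moderate"` or `"dark"` (see [skin_presets()]).
#' @param phase Cardiac phase, `"diastole"` or `"systole"`.
#' @param mode Sensor geometry, `"transmittance"` (detector opposite the
#'   source) or `"reflectance"` (detector adjacent, offset `sds` along +x).
#' @param sds Source-detector separation in mm; required in reflectance mode
#'   (one of 1, 3, 5, 7, 9), ignored in transmittance mode.
#' @param n_photons Number of photon packets to launch.
#' @param seed Integer seed; identical seed and scenario give bit-identical
#'   results.
#' @param beam_radius Standard deviation of the Gaussian launch beam, mm.
#' @param detector_radius Radius of the detector disc, mm.
#' @param spo2 Arterial oxygen saturation (fraction), default 1.
#' @param sublayers Skin sublayer composition table, default
#'   [skin_sublayers()]. Must keep the six sublayer names, positive
#'   thicknesses summing to 0.95 mm, and valid volume fractions.
#' @param v_water_epidermis Water fraction of the epidermis and (with the
#'   stratum corneum's own entry) of the stratum corneum, via `sublayers`.
#'   Present for documentation; override through `sublayers`.
#' @param bone_radius Radius of the bone cylinder, mm.
#' @param lateral_max Lateral kill distance from the source axis, mm; photons
#'   wandering further are terminated as lost weight.
#' @param roulette_threshold Packet weight below which Russian roulette is
#'   played.
#' @param roulette_m Roulette survival factor (survivors keep weight
#'   `w * roulette_m` with probability `1/roulette_m`).
#' @return An object of class `ppg_scenario`.
#' @export
#' @examples
#' scenario(660, "dark", "diastole", "reflectance", sds = 3, n_photons = 1e4)
scenario <- function(wavelength, skin_type = c("light", "moderate", "dark"),
                     phase = c("diastole", "systole"),
                     mode = c("transmittance", "reflectance"),
                     sds = NULL, n_photons = 1e6, seed = 1L,
                     beam_radius = 0.25, detector_radius = 0.5,
                     spo2 = 1, sublayers = skin_sublayers(),
                     v_water_epidermis = 0.65,
                     bone_radius = 2.5, lateral_max = 20,
                     roulette_threshold = 1e-4, roulette_m = 10) {
  check_wavelength(wavelength)
  skin_type <- rlang::arg_match(skin_type)
  phase <- rlang::arg_match(phase)
  mode <- rlang::arg_match(mode)
  if (mode == "reflectance") {
    if (is.null(sds) || !is.numeric(sds) || length(sds) != 1 || sds <= 0) {
      rlang::abort("reflectance mode needs a positive `sds` (mm)",
                   class = "fingerppg_invalid_parameter")
    }
  } else {
    sds <- NA_real_
  }
  stopifnot(
    n_photons >= 0, beam_radius > 0, detector_radius > 0,
    spo2 >= 0, spo2 <= 1, bone_radius > 0, lateral_max > 0,
    roulette_threshold > 0, roulette_m > 1
  )
  validate_sublayers(sublayers)

  structure(
    list(
      wavelength = wavelength, skin_type = skin_type, phase = phase,
      mode = mode, sds = sds, n_photons = as.double(n_photons),
      seed = as.integer(seed), beam_radius = beam_radius,
      detector_radius = detector_radius, spo2 = spo2,
      sublayers = sublayers, v_water_epidermis = v_water_epidermis,
      bone_radius = bone_radius, lateral_max = lateral_max,
      roulette_threshold = roulette_threshold, roulette_m = roulette_m
    ),
    class = "ppg_scenario"
  )
}

validate_sublayers <- function(sublayers) {
  wanted <- skin_sublayers()$sublayer
  if (!is.data.frame(sublayers) || !identical(sublayers$sublayer, wanted)) {
    rlang::abort(
      "`sublayers` must keep the six named skin sublayers in order",
      class = "fingerppg_invalid_parameter"
    )
  }
  th <- sublayers$thickness
  if (any(th <= 0) || abs(sum(th) - 0.95) > 1e-9) {
    rlang::abort(
      "sublayer thicknesses must be positive and sum to 0.95 mm",
      class = "fingerppg_invalid_parameter"
    )
  }
  vb <- sublayers$v_blood_diastole
  vw <- sublayers$v_water
  if (any(vb < 0) || any(vw < 0) || any(vw > 1) || any(2 * vb > 1)) {
    rlang::abort(
      paste0("volume fractions must lie in [0, 1] with ",
             "2 * v_blood_diastole <= 1 (systolic doubling must remain a ",
             "valid mixture)"),
      class = "fingerppg_invalid_parameter"
    )
  }
  invisible(sublayers)
}

#' @export
print.ppg_scenario <- function(x, ...) {
  sds <- if (is.na(x$sds)) "" else paste0(", sds = ", x$sds, " mm")
  cat(sprintf(
    "<ppg_scenario> %d nm, %s skin, %s, %s%s, %g photons, seed %d\n",
    x$wavelength, x$skin_type, x$phase, x$mode, sds, x$n_photons, x$seed
  ))
  invisible(x)
}

#' Read or write a scenario configuration file
#'
#' Scenarios serialise to YAML (or JSON, which YAML parses) with keys
#' `wavelength_nm`, `skin_type`, `phase`, `mode`, `sds_mm`, `n_photons`,
#' `seed`, `beam_radius_mm`, `detector_radius_mm` and an optional
#' `sublayers` override table. Unknown keys are rejected.
#'
#' @param path File path.
#' @param config A `ppg_scenario`.
#' @return `read_scenario()` returns a `ppg_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("wavelength_nm", "skin_type", "phase", "mode", "sds_mm",
               "n_photons", "seed", "beam_radius_mm", "detector_radius_mm",
               "spo2", "sublayers", "bone_radius_mm", "lateral_max_mm",
               "roulette_threshold", "roulette_m")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    rlang::abort(
      paste0("unknown scenario keys: ", paste(unknown, collapse = ", ")),
      class = "fingerppg_invalid_parameter"
    )
  }
  sub <- if (is.null(raw$sublayers)) skin_sublayers() else {
    base <- skin_sublayers()
    ov <- dplyr::bind_rows(lapply(raw$sublayers, tibble::as_tibble))
    dplyr::rows_update(base, ov, by = "sublayer")
  }
  args <- list(
    wavelength = raw$wavelength_nm, skin_type = raw$skin_type,
    phase = raw$phase %||% "diastole", mode = raw$mode,
    sds = raw$sds_mm, sublayers = sub
  )
  if (!is.null(raw$n_photons)) args$n_photons <- raw$n_photons
  if (!is.null(raw$seed)) args$seed <- raw$seed
  if (!is.null(raw$beam_radius_mm)) args$beam_radius <- raw$beam_radius_mm
  if (!is.null(raw$detector_radius_mm)) {
    args$detector_radius <- raw$detector_radius_mm
  }
  if (!is.null(raw$spo2)) args$spo2 <- raw$spo2
  if (!is.null(raw$bone_radius_mm)) args$bone_radius <- raw$bone_radius_mm
  if (!is.null(raw$lateral_max_mm)) args$lateral_max <- raw$lateral_max_mm
  if (!is.null(raw$roulette_threshold)) {
    args$roulette_threshold <- raw$roulette_threshold
  }
  if (!is.null(raw$roulette_m)) args$roulette_m <- raw$roulette_m
  do.call(scenario, args)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "ppg_scenario"))
  out <- list(
    wavelength_nm = config$wavelength, skin_type = config$skin_type,
    phase = config$phase, mode = config$mode,
    n_photons = config$n_photons, seed = config$seed,
    beam_radius_mm = config$beam_radius,
    detector_radius_mm = config$detector_radius, spo2 = config$spo2,
    bone_radius_mm = config$bone_radius,
    lateral_max_mm = config$lateral_max,
    roulette_threshold = config$roulette_threshold,
    roulette_m = config$roulette_m
  )
  if (!is.na(config$sds)) out$sds_mm <- config$sds
  if (!identical(config$sublayers, skin_sublayers())) {
    out$sublayers <- purrr::transpose(as.list(config$sublayers))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
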