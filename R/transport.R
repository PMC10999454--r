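#' Elementary Monte Carlo transport rules
#'
#' The building blocks of the photon random walk, exported from the compiled
#' engine so each rule can be exercised in isolation (the engine itself calls
#' the same code):
#'
#' * `sample_step(xi, mu_t)` - free-path length \eqn{-\ln(\xi)/\mu_t} (mm)
#'   for uniform deviates `xi` in (0, 1\] and total attenuation `mu_t`.
#' * `hg_cos_theta(g, xi)` - deflection-angle cosine drawn from the
#'   Henyey-Greenstein phase function by inverse CDF; `g = 0` reduces to the
#'   isotropic `2 * xi - 1`.
#' * `update_direction(u, cos_theta, phi)` - rotates a unit direction by
#'   polar angle `acos(cos_theta)` and azimuth `phi`.
#' * `fresnel_reflectance(n1, n2, cos_i)` - unpolarised Fresnel reflection
#'   probability; 1 beyond the critical angle.
#' * `roulette_weight(w, xi, threshold, survival_factor)` - Russian roulette:
#'   weights below `threshold` survive with probability
#'   `1/survival_factor` (boosted by `survival_factor`) or terminate to 0;
#'   expected weight is conserved.
#' * `launch_positions(n, seed, beam_sigma)` - the Gaussian-beam launch
#'   positions and (orthogonal) launch direction for photons `0..n-1` of a
#'   run seeded with `seed`.
#'
#' @param xi Uniform deviate(s) in (0, 1\] (for `sample_step`) or \[0, 1).
#' @param mu_t Total attenuation coefficient, mm^-1 (> 0).
#' @param g Henyey-Greenstein anisotropy in \[-1, 1\].
#' @param u Direction-cosine vector of length 3 (unit norm).
#' @param cos_theta Deflection cosine in \[-1, 1\].
#' @param phi Azimuthal angle in radians.
#' @param n1,n2 Refractive indices on the incident and far side.
#' @param cos_i Cosine of the incidence angle in \[0, 1\].
#' @param w Photon packet weight(s).
#' @param threshold Roulette trigger weight.
#' @param survival_factor Roulette survival factor (> 1).
#' @param n Number of photons.
#' @param seed Run seed.
#' @param beam_sigma Gaussian beam standard deviation, mm.
#' @name transport-kernels
NULL

#' Run photon transport through a model
#'
#' Launches weighted photon packets into a [build_finger()] model (or a
#' [homogeneous_slab()]) and propagates each by the hop-drop-spin cycle
#' until it is detected, escapes undetected, wanders beyond the lateral kill
#' distance, or loses the roulette. Weight bookkeeping is exact: specular +
#' absorbed + detected + escaped + lateral + roulette net = launched weight.
#'
#' Each photon draws from its own RNG stream seeded by `(seed, photon
#' index)`, so results are bit-identical for a given seed regardless of how
#' the work is batched.
#'
#' @param model A `finger_model`.
#' @param n_photons Number of packets to launch.
#' @param seed Integer seed.
#' @param mode `"transmittance"` or `"reflectance"`.
#' @param sds Source-detector separation, mm (reflectance only).
#' @param detector_radius Detector disc radius, mm.
#' @param beam_radius Gaussian beam standard deviation, mm.
#' @param lateral_max Lateral kill distance, mm.
#' @param roulette_threshold,roulette_m Russian roulette parameters.
#' @param record_paths Record (x, z) interaction vertices of detected
#'   photons (needed for [profile_histogram()]).
#' @param max_paths Cap on the number of recorded trajectories.
#' @return A `transport_tallies` object; see [tidy.transport_tallies()] and
#'   [glance.transport_tallies()].
#' @export
#' @examples
#' slab <- homogeneous_slab(mua = 1, mus = 0, thickness = 1)
#' t <- run_transport(slab, 2000, seed = 7, detector_radius = 50)
#' glance(t)$i_detected  # ~ exp(-1), Beer-Lambert
run_transport <- function(model, n_photons, seed = 1L,
                          mode = c("transmittance", "reflectance"),
                          sds = 0, detector_radius = 0.5,
                          beam_radius = 0.25, lateral_max = 20,
                          roulette_threshold = 1e-4, roulette_m = 10,
                          record_paths = FALSE, max_paths = 50000L) {
  stopifnot(inherits(model, "finger_model"), n_photons >= 0)
  mode <- rlang::arg_match(mode)
  res <- rt_run(
    n_photons = as.integer(n_photons), seed = as.double(seed),
    z_edges = model$z_edges,
    slab_region = as.integer(model$slab_region - 1L),
    muscle_slab = as.integer(model$muscle_slab - 1L),
    bone_region = as.integer(model$bone_region - 1L),
    bone_zc = model$bone_zc, bone_radius = model$bone_radius,
    mua = model$regions$mua, mus = model$regions$mus, g = model$regions$g,
    n_tissue = model$n_tissue, n_ambient = model$n_ambient,
    mode = if (mode == "transmittance") 0L else 1L,
    sds = if (is.na(sds) || is.null(sds)) 0 else sds,
    det_radius = detector_radius, beam_sigma = beam_radius,
    lateral_max = lateral_max, roulette_threshold = roulette_threshold,
    roulette_m = roulette_m, record_paths = record_paths,
    max_paths = as.integer(max_paths)
  )
  structure(
    list(
      n_launched = res$n_launched,
      n_detected = res$n_detected,
      w_detected = res$w_detected,
      specular = res$specular,
      absorbed = stats::setNames(res$absorbed, model$regions$region),
      detected_absorbed = stats::setNames(res$detected_absorbed,
                                          model$regions$region),
      escaped = res$escaped,
      lateral = res$lateral,
      roulette_net = res$roulette_net,
      records = tibble::as_tibble(res$records),
      paths = res$paths,
      model = model,
      mode = mode, sds = sds, seed = as.integer(seed)
    ),
    class = "transport_tallies"
  )
}

#' Run one configured scenario
#'
#' Builds the finger model for a [scenario()] and runs its photon transport.
#'
#' @param config A `ppg_scenario`.
#' @param record_paths Record detected-photon trajectories.
#' @return A `transport_tallies` object.
#' @export
#' @examples
#' t <- run_scenario(scenario(940, "light", n_photons = 2e4, seed = 3))
#' glance(t)
run_scenario <- function(config, record_paths = FALSE) {
  stopifnot(inherits(config, "ppg_scenario"))
  model <- build_finger(config)
  run_transport(
    model, n_photons = config$n_photons, seed = config$seed,
    mode = config$mode, sds = config$sds,
    detector_radius = config$detector_radius,
    beam_radius = config$beam_radius, lateral_max = config$lateral_max,
    roulette_threshold = config$roulette_threshold,
    roulette_m = config$roulette_m, record_paths = record_paths
  )
}

#' @export
print.transport_tallies <- function(x, ...) {
  cat(sprintf(
    "<transport_tallies> %s mode: %g launched, %g detected (weight %.4g)\n",
    x$mode, x$n_launched, x$n_detected, x$w_detected
  ))
  cat(sprintf(
    "  specular %.4g | absorbed %.4g | escaped %.4g | lateral %.4g | roulette %.4g\n",
    x$specular, sum(x$absorbed), x$escaped, x$lateral, x$roulette_net
  ))
  invisible(x)
}

#' Tidy detected-photon records
#'
#' One row per detected photon: exit position (`x`, `y`), refracted exit
#' direction cosines, residual weight `w`, total optical pathlength
#' (`pathlength`, mm) and maximum penetration depth (`z_max`, mm).
#'
#' @param x A `transport_tallies`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.transport_tallies <- function(x, ...) {
  x$records
}

#' One-row run summary
#'
#' Counts, weight ledger and derived intensities for a transport run.
#' `i_detected` is the detected intensity (detected weight over launched
#' weight); `weight_balance` is the relative weight-conservation error and
#' should be at numerical zero.
#'
#' @param x A `transport_tallies`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.transport_tallies <- function(x, ...) {
  total <- x$specular + sum(x$absorbed) + x$w_detected + x$escaped +
    x$lateral + x$roulette_net
  tibble::tibble(
    mode = x$mode,
    sds = x$sds,
    n_launched = x$n_launched,
    n_detected = x$n_detected,
    w_detected = x$w_detected,
    i_detected = if (x$n_launched > 0) x$w_detected / x$n_launched else
      NA_real_,
    specular = x$specular,
    absorbed = sum(x$absorbed),
    escaped = x$escaped,
    lateral = x$lateral,
    roulette_net = x$roulette_net,
    weight_balance = if (x$n_launched > 0) {
      (total - x$n_launched) / x$n_launched
    } else 0
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
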