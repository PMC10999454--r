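#' Build the resolved finger model for a scenario
#'
#' Assembles the 13.0 mm finger as an ordered stack of slabs along the depth
#' axis z (0 at the illuminated surface): six skin sublayers (0.95 mm), fat
#' (0.5 mm), muscle (10.1 mm) containing a cylindrical bone whose axis runs
#' along the finger length (y) at the mid-depth of the muscle slab, fat
#' (0.5 mm) and the six skin sublayers mirrored. Each region's optical
#' properties are resolved for the scenario's wavelength, skin type and
#' cardiac phase: the epidermis uses [epidermis_mua()] with the preset
#' melanosome fraction, the four dermal sublayers use [dermal_mua()] (systole
#' doubles their blood volume), the stratum corneum is bloodless and
#' melanin-free, and fat, muscle and bone use the tabulated literature
#' values. All interior interfaces are index-matched at n = 1.4; only the
#' two outer surfaces (n 1.4 to 1.0) reflect and refract.
#'
#' @param config A [scenario()].
#' @return An object of class `finger_model`: a list with a `regions` tibble
#'   (`region`, `tissue`, `z_low`, `z_high`, `mua`, `mus`, `g`, `n`), the
#'   slab decomposition and the bone cylinder parameters.
#' @export
#' @examples
#' m <- build_finger(scenario(940, "dark", n_photons = 1))
#' sum(m$regions$z_high - m$regions$z_low, na.rm = TRUE)  # 13 mm of slabs
build_finger <- function(config) {
  stopifnot(inherits(config, "ppg_scenario"))
  wl <- config$wavelength
  sub <- config$sublayers
  preset <- skin_presets()
  v_mel <- preset$v_mel[preset$skin_type == config$skin_type]

  skin_mus <- lookup_property("skin", wl, "mus")
  skin_g <- lookup_property("skin", wl, "g")

  sub_mua <- function(row) {
    if (row$sublayer == "stratum_corneum") {
      row$v_water * water_mua(wl) + (1 - row$v_water) * baseline_mua(wl)
    } else if (row$sublayer == "epidermis") {
      epidermis_mua(v_mel, wl, v_water = row$v_water)
    } else {
      dermal_mua(row, config$phase, wl, config$spo2)
    }
  }

  skin_tbl <- function(mirrored) {
    s <- sub
    if (mirrored) s <- s[rev(seq_len(nrow(s))), ]
    tibble::tibble(
      tissue = s$sublayer,
      thickness = s$thickness,
      mua = purrr::map_dbl(seq_len(nrow(s)), function(i) sub_mua(s[i, ])),
      mus = skin_mus,
      g = skin_g
    )
  }

  bulk <- function(tissue, thickness) {
    tibble::tibble(
      tissue = tissue, thickness = thickness,
      mua = lookup_property(tissue, wl, "mua"),
      mus = lookup_property(tissue, wl, "mus"),
      g = lookup_property(tissue, wl, "g")
    )
  }

  slabs <- dplyr::bind_rows(
    skin_tbl(FALSE),
    bulk("fat", 0.5),
    bulk("muscle", 10.1),
    bulk("fat", 0.5),
    skin_tbl(TRUE)
  )
  z_edges <- c(0, cumsum(slabs$thickness))
  n_slab <- nrow(slabs)

  muscle_slab <- which(slabs$tissue == "muscle")  # single muscle slab
  bone_zc <- (z_edges[muscle_slab] + z_edges[muscle_slab + 1]) / 2
  if (config$bone_radius >=
      (z_edges[muscle_slab + 1] - z_edges[muscle_slab]) / 2) {
    rlang::abort("bone cylinder must lie strictly inside the muscle slab",
                 class = "fingerppg_invalid_parameter")
  }

  regions <- tibble::tibble(
    region = c(
      paste0(slabs$tissue[seq_len(7)], "_top")[seq_len(7)],
      "muscle", "bone",
      paste0(slabs$tissue[9:n_slab], "_bottom")
    ),
    tissue = c(slabs$tissue[seq_len(7)], "muscle", "bone",
               slabs$tissue[9:n_slab]),
    z_low = c(z_edges[seq_len(7)], z_edges[8], NA_real_,
              z_edges[9:n_slab]),
    z_high = c(z_edges[2:8], z_edges[9], NA_real_, z_edges[10:(n_slab + 1)]),
    mua = c(slabs$mua[seq_len(8)], lookup_property("bone", wl, "mua"),
            slabs$mua[9:n_slab]),
    mus = c(slabs$mus[seq_len(8)], lookup_property("bone", wl, "mus"),
            slabs$mus[9:n_slab]),
    g = c(slabs$g[seq_len(8)], lookup_property("bone", wl, "g"),
          slabs$g[9:n_slab]),
    n = 1.4
  )
  # slab index (1-based) -> region row
  slab_region <- c(seq_len(8), 10:(n_slab + 1))

  structure(
    list(
      regions = regions,
      z_edges = z_edges,
      slab_region = slab_region,
      muscle_slab = muscle_slab,
      bone_region = which(regions$region == "bone"),
      bone_zc = bone_zc,
      bone_radius = config$bone_radius,
      n_tissue = 1.4,
      n_ambient = 1.0,
      total_thickness = z_edges[length(z_edges)]
    ),
    class = "finger_model"
  )
}

#' @export
print.finger_model <- function(x, ...) {
  cat(sprintf(
    "<finger_model> %d regions, %.1f mm thick, bone r = %.2f mm at z = %.2f mm\n",
    nrow(x$regions), x$total_thickness, x$bone_radius, x$bone_zc
  ))
  print(x$regions, n = nrow(x$regions))
  invisible(x)
}

#' Region lookup inside a model
#'
#' Maps an interior point to the unique region that contains it. The z axis
#' is depth (0 at the illuminated surface); the bone test applies inside the
#' muscle slab, where points within `bone_radius` of the bone axis (along y
#' at x = 0, depth `bone_zc`) belong to the bone.
#'
#' @param model A `finger_model` (or homogeneous slab from
#'   [homogeneous_slab()]).
#' @param x,z Coordinates in mm (any y; the model is laterally unbounded and
#'   y-invariant).
#' @return The region name, a character scalar.
#' @export
#' @examples
#' m <- build_finger(scenario(660, "light", n_photons = 1))
#' region_at(m, 0, 0.01)   # "stratum_corneum_top"
#' region_at(m, 0, m$bone_zc)  # "bone"
region_at <- function(model, x, z) {
  stopifnot(inherits(model, "finger_model"))
  if (z < model$z_edges[1] || z >= model$z_edges[length(model$z_edges)]) {
    rlang::abort("point lies outside the model",
                 class = "fingerppg_internal_consistency")
  }
  slab <- findInterval(z, model$z_edges, rightmost.closed = FALSE)
  if (slab == model$muscle_slab &&
      x^2 + (z - model$bone_zc)^2 < model$bone_radius^2) {
    return(model$regions$region[model$bone_region])
  }
  model$regions$region[model$slab_region[slab]]
}

#' Homogeneous validation slab
#'
#' A single-layer model of the same class the transport engine consumes,
#' used for analytic validation (e.g. the scattering-free Beer-Lambert
#' transmission oracle) and for studying the engine in isolation.
#'
#' @param mua,mus,g Optical properties of the medium (mm^-1, mm^-1,
#'   dimensionless).
#' @param thickness Slab thickness in mm.
#' @param n_tissue,n_ambient Refractive indices inside and outside; equal
#'   values disable all Fresnel events.
#' @return A `finger_model` with one region and no bone.
#' @export
#' @examples
#' homogeneous_slab(mua = 1, mus = 0, g = 0, thickness = 1)
homogeneous_slab <- function(mua, mus, g = 0, thickness = 1,
                             n_tissue = 1.0, n_ambient = 1.0) {
  stopifnot(mua >= 0, mus >= 0, mua + mus > 0, thickness > 0)
  structure(
    list(
      regions = tibble::tibble(
        region = "medium", tissue = "medium", z_low = 0, z_high = thickness,
        mua = mua, mus = mus, g = g, n = n_tissue
      ),
      z_edges = c(0, thickness),
      slab_region = 1L,
      muscle_slab = -1L,
      bone_region = -1L,
      bone_zc = 0,
      bone_radius = 0,
      n_tissue = n_tissue,
      n_ambient = n_ambient,
      total_thickness = thickness
    ),
    class = "finger_model"
  )
}
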