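#' AC and DC components of a simulated PPG signal
#'
#' From the detected intensities of a paired systole/diastole run,
#' `AC = I_d - I_s` (the pulsatile component: systolic blood-volume doubling
#' only adds absorption, so the systolic intensity is the smaller one) and
#' `DC = I_s` (the baseline). The perfusion-index-like `ratio` is `AC / DC`.
#'
#' @param i_systole,i_diastole Detected systolic and diastolic intensities
#'   (detected weight over launched weight), in \[0, 1\]. Vectorised.
#' @return A tibble with columns `i_systole`, `i_diastole`, `ac`, `dc`,
#'   `ratio`. A zero systolic intensity leaves `ratio` as `NA` (the run is
#'   treated as non-converged rather than dividing by zero).
#' @export
#' @examples
#' ac_dc(0.4, 0.5)
ac_dc <- function(i_systole, i_diastole) {
  if (any(i_systole < 0) || any(i_diastole < 0) ||
      any(i_systole > 1) || any(i_diastole > 1)) {
    rlang::abort("intensities must lie in [0, 1]",
                 class = "fingerppg_invalid_parameter")
  }
  tibble::tibble(
    i_systole = i_systole,
    i_diastole = i_diastole,
    ac = i_diastole - i_systole,
    dc = i_systole,
    ratio = ifelse(i_systole > 0, (i_diastole - i_systole) / i_systole,
                   NA_real_)
  )
}

#' Convergence rate of a run
#'
#' The precision diagnostic `Q = 1 / sqrt(N)` with `N` the detected-photon
#' count. A run passes the convergence filter when `Q <= 0.001`, i.e. at
#' least 10^6 detected photons; runs failing the filter are flagged, not
#' dropped.
#'
#' @param n_detected Detected photon count(s), non-negative. Vectorised.
#' @return A tibble with columns `n`, `q` (`Inf` for `n = 0`) and
#'   `converged`.
#' @export
#' @examples
#' convergence(c(1791, 341, 55))
convergence <- function(n_detected) {
  if (any(n_detected < 0)) {
    rlang::abort("`n_detected` must be non-negative",
                 class = "fingerppg_invalid_parameter")
  }
  tibble::tibble(
    n = n_detected,
    q = ifelse(n_detected > 0, 1 / sqrt(n_detected), Inf),
    converged = n_detected >= 1e6
  )
}

#' Relative absorbance of detected photons per region
#'
#' Shares out the weight deposited along detected photons' histories over
#' the model regions: for each region, 100 times its detected-photon
#' deposition over the total. Undetected photons do not contribute. The
#' percentages sum to 100.
#'
#' @param tallies A `transport_tallies` with at least one detected photon.
#' @return A tibble with columns `region`, `tissue`, `weight`, `percent`,
#'   ordered as in the model.
#' @export
relative_absorbance <- function(tallies) {
  stopifnot(inherits(tallies, "transport_tallies"))
  if (tallies$n_detected == 0) {
    rlang::abort("no detected photons: relative absorbance is undefined",
                 class = "fingerppg_undefined")
  }
  w <- tallies$detected_absorbed
  tibble::tibble(
    region = names(w),
    tissue = tallies$model$regions$tissue,
    weight = unname(w),
    percent = 100 * unname(w) / sum(w)
  )
}

#' Pathlength and penetration-depth statistics of detected photons
#'
#' Arithmetic means over detected photons of the total optical pathlength
#' and of the per-photon maximum depth. The mean pathlength is never smaller
#' than the mean penetration depth.
#'
#' @param tallies A `transport_tallies` (or a tibble of detection records
#'   with columns `pathlength` and `z_max`).
#' @return A one-row tibble with `n`, `mean_pathlength` and
#'   `mean_penetration_depth` (mm).
#' @export
path_stats <- function(tallies) {
  records <- if (inherits(tallies, "transport_tallies")) {
    tallies$records
  } else {
    tallies
  }
  if (nrow(records) == 0) {
    rlang::abort("no detected photons: path statistics are undefined",
                 class = "fingerppg_undefined")
  }
  tibble::tibble(
    n = nrow(records),
    mean_pathlength = mean(records$pathlength),
    mean_penetration_depth = mean(records$z_max)
  )
}

#' Symmetric percentage difference
#'
#' `100 * |a - b| / ((a + b) / 2)`: the mean-based symmetric percentage
#' difference used to compare path statistics between skin-type pairs, so
#' neither group serves as the reference.
#'
#' @param a,b Positive values. Vectorised.
#' @return Percentage difference(s).
#' @export
#' @examples
#' percent_difference(1, 3)  # 100
percent_difference <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) {
    rlang::abort("`a` and `b` must be positive",
                 class = "fingerppg_invalid_parameter")
  }
  100 * abs(a - b) / ((a + b) / 2)
}

#' Photon propagation profile histogram
#'
#' Bins the (x, z) interaction vertices of detected photons onto a fixed
#' 200 x 200 grid (the profile resolution used throughout), giving the
#' occupancy map of where detected light travelled in the finger
#' cross-section. Requires a run made with `record_paths = TRUE`.
#'
#' @param tallies A `transport_tallies` run with `record_paths = TRUE`.
#' @param n_bins Number of bins per axis.
#' @param xlim Lateral extent of the grid, mm; defaults to symmetric about
#'   the source over the lateral kill distance.
#' @return A `profile_histogram`: counts matrix (`n_bins` x `n_bins`,
#'   rows = x, columns = z) plus bin-edge vectors `x_edges`, `z_edges`.
#' @export
profile_histogram <- function(tallies, n_bins = 200, xlim = c(-20, 20)) {
  stopifnot(inherits(tallies, "transport_tallies"))
  if (is.null(tallies$paths)) {
    rlang::abort(
      "run the scenario with `record_paths = TRUE` to build profiles",
      class = "fingerppg_invalid_parameter"
    )
  }
  zlim <- c(tallies$model$z_edges[1],
            tallies$model$z_edges[length(tallies$model$z_edges)])
  x_edges <- seq(xlim[1], xlim[2], length.out = n_bins + 1)
  z_edges <- seq(zlim[1], zlim[2], length.out = n_bins + 1)
  acc <- numeric(n_bins * n_bins)
  for (m in tallies$paths) {
    if (nrow(m) == 0) next
    ix <- findInterval(m[, 1], x_edges, rightmost.closed = TRUE)
    iz <- findInterval(m[, 2], z_edges, rightmost.closed = TRUE)
    keep <- ix >= 1 & ix <= n_bins & iz >= 1 & iz <= n_bins
    if (!any(keep)) next
    acc <- acc + tabulate(ix[keep] + (iz[keep] - 1L) * n_bins,
                          nbins = n_bins * n_bins)
  }
  counts <- matrix(as.integer(acc), n_bins, n_bins)
  structure(
    list(counts = counts, x_edges = x_edges, z_edges = z_edges,
         n_vertices = sum(counts),
         n_photons = length(tallies$paths)),
    class = "profile_histogram"
  )
}

#' @export
print.profile_histogram <- function(x, ...) {
  cat(sprintf(
    "<profile_histogram> %d x %d bins, %d vertices from %d detected photons\n",
    nrow(x$counts), ncol(x$counts), x$n_vertices, x$n_photons
  ))
  invisible(x)
}

#' Plot a photon propagation profile
#'
#' Heat map of the detected-photon occupancy grid on a log1p colour scale,
#' with depth increasing downward as in the finger geometry.
#'
#' @param object A [profile_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.profile_histogram <- function(object, ...) {
  xm <- (object$x_edges[-1] + object$x_edges[-length(object$x_edges)]) / 2
  zm <- (object$z_edges[-1] + object$z_edges[-length(object$z_edges)]) / 2
  df <- tidyr::expand_grid(xi = seq_along(xm), zi = seq_along(zm))
  df$x <- xm[df$xi]
  df$z <- zm[df$zi]
  df$count <- object$counts[cbind(df$xi, df$zi)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$z,
                                   fill = log1p(.data$count))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "log(1 + visits)") +
    ggplot2::labs(x = "x (mm)", y = "depth z (mm)",
                  title = "Detected-photon propagation profile")
}
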