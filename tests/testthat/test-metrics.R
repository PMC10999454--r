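test_that("AC/DC components follow their defining identities", {
  m <- ac_dc(0.4, 0.5)
  expect_equal(m$ac, 0.1)
  expect_equal(m$dc, 0.4)
  expect_equal(m$ratio, 0.25)

  expect_equal(ac_dc(0.3, 0.3)$ac, 0)
  # zero systolic intensity: ratio undefined, surfaced as NA
  expect_true(is.na(ac_dc(0, 0.1)$ratio))
  expect_error(ac_dc(-0.1, 0.5), class = "fingerppg_invalid_parameter")
})

test_that("convergence rate reproduces the printed diagnostics", {
  published <- tibble::tribble(
    ~n,      ~q,
    1791,    0.024,
    341,     0.054,
    55,      0.135,
    9655,    0.010,
    6846,    0.012,
    4408,    0.015
  )
  got <- convergence(published$n)
  expect_equal(round(got$q, 3), published$q)
  expect_false(any(got$converged))

  exact <- convergence(1e6)
  expect_identical(exact$q, 0.001)
  expect_true(exact$converged)
  expect_identical(convergence(0)$q, Inf)
  expect_error(convergence(-1), class = "fingerppg_invalid_parameter")
})

test_that("relative absorbance shares detected deposition over regions", {
  t <- run_scenario(quick_scenario(660, "dark", mode = "reflectance",
                                   sds = 1, n_photons = 3e4))
  ra <- relative_absorbance(t)
  expect_equal(sum(ra$percent), 100, tolerance = 1e-6)
  expect_true(all(ra$percent >= 0))
  expect_identical(ra$region, names(t$detected_absorbed))
  # melanin makes the epidermis the dominant absorber for detected photons
  epi <- ra$percent[ra$tissue == "epidermis"]
  expect_gt(sum(epi), ra$percent[ra$region == "stratum_corneum_top"])

  # single-region medium takes all of it
  slab <- homogeneous_slab(mua = 0.5, mus = 5, g = 0.9, thickness = 0.5)
  ts <- run_transport(slab, 5e3, seed = 2, detector_radius = 1000,
                      lateral_max = 1e3)
  expect_equal(relative_absorbance(ts)$percent, 100)

  empty <- run_scenario(quick_scenario(n_photons = 0))
  expect_error(relative_absorbance(empty), class = "fingerppg_undefined")
})

test_that("path statistics summarise detected photons", {
  one <- tibble::tibble(pathlength = 17.3, z_max = 4.2)
  ps <- path_stats(one)
  expect_equal(ps$mean_pathlength, 17.3)
  expect_equal(ps$mean_penetration_depth, 4.2)

  t <- run_scenario(quick_scenario(940, "light", mode = "reflectance",
                                   sds = 1, n_photons = 2e4))
  ps <- path_stats(t)
  expect_gte(ps$mean_pathlength, ps$mean_penetration_depth)
  expect_gt(ps$mean_penetration_depth, 0)
  expect_error(path_stats(tibble::tibble(pathlength = numeric(),
                                         z_max = numeric())),
               class = "fingerppg_undefined")
})

test_that("percentage difference is the symmetric mean-based form", {
  expect_identical(percent_difference(3, 3), 0)
  expect_equal(percent_difference(1, 3), 100)
  expect_identical(percent_difference(2, 5), percent_difference(5, 2))
  expect_error(percent_difference(0, 1),
               class = "fingerppg_invalid_parameter")
})

test_that("profile histograms bin detected trajectories conservatively", {
  # forward-scattering medium: one photon's vertices sit in one x-column
  slab <- homogeneous_slab(mua = 0.2, mus = 2, g = 1, thickness = 5)
  t <- run_transport(slab, 300, seed = 9, detector_radius = 1000,
                     lateral_max = 1e3, record_paths = TRUE)
  expect_gt(t$n_detected, 0)
  h <- profile_histogram(t, n_bins = 50, xlim = c(-2, 2))
  expect_identical(dim(h$counts), c(50L, 50L))
  expect_true(all(h$counts >= 0))
  # conservation: every recorded vertex lands in exactly one bin
  n_vertices <- sum(vapply(t$paths, nrow, integer(1)))
  expect_identical(h$n_vertices, n_vertices)
  # straight trajectories occupy a single x-column each
  for (m in t$paths[seq_len(min(5, length(t$paths)))]) {
    expect_lt(diff(range(m[, 1])), 1e-9)
  }

  # runs without trajectories cannot build profiles
  t2 <- run_transport(slab, 10, seed = 9, detector_radius = 1000)
  expect_error(profile_histogram(t2), class = "fingerppg_invalid_parameter")

  p <- autoplot(h)
  expect_s3_class(p, "ggplot")
})

test_that("reflectance occupancy sits above transmittance occupancy", {
  refl <- run_scenario(quick_scenario(940, "light", mode = "reflectance",
                                      sds = 1, n_photons = 1e4),
                       record_paths = TRUE)
  trans <- run_scenario(quick_scenario(940, "light", n_photons = 1e4),
                        record_paths = TRUE)
  hr <- profile_histogram(refl, n_bins = 100)
  ht <- profile_histogram(trans, n_bins = 100)
  zm <- (hr$z_edges[-1] + hr$z_edges[-length(hr$z_edges)]) / 2
  depth_mean <- function(h) {
    sum(colSums(h$counts) * zm) / sum(h$counts)
  }
  expect_lt(depth_mean(hr), depth_mean(ht))
})
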