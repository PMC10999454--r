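balance_of <- function(tallies) glance(tallies)$weight_balance

test_that("scattering-free slab reproduces Beer-Lambert transmission", {
  for (mua in c(0.5, 1, 2)) {
    slab <- homogeneous_slab(mua = mua, mus = 0, thickness = 1)
    t <- run_transport(slab, 4e4, seed = 7 + mua,
                       detector_radius = 1000, lateral_max = 1e4)
    p <- exp(-mua)
    se <- sqrt(p * (1 - p) / t$n_launched)
    expect_lt(abs(glance(t)$i_detected - p), 3 * se)
    expect_lt(abs(balance_of(t)), 1e-6)
    # ballistic photons keep full weight and a straight 1 mm path
    expect_true(all(t$records$w == 1))
    expect_true(all(abs(t$records$pathlength - 1) < 1e-9))
  }
})

test_that("weight bookkeeping is exact across modes and wavelengths", {
  runs <- list(
    run_scenario(quick_scenario(660, "dark", n_photons = 5e3)),
    run_scenario(quick_scenario(940, "light", phase = "systole",
                                n_photons = 5e3)),
    run_scenario(quick_scenario(660, "moderate", mode = "reflectance",
                                sds = 3, n_photons = 5e3)),
    run_scenario(quick_scenario(940, "dark", mode = "reflectance",
                                sds = 1, n_photons = 5e3))
  )
  for (t in runs) {
    expect_lt(abs(balance_of(t)), 1e-6)
    expect_true(all(t$absorbed >= 0))
    expect_gte(t$escaped, 0)
    expect_gte(t$lateral, 0)
  }
})

test_that("specular reflection takes the normal-incidence Fresnel share", {
  t <- run_scenario(quick_scenario(n_photons = 1000))
  expect_equal(t$specular / t$n_launched, ((1 - 1.4) / (1 + 1.4))^2,
               tolerance = 1e-12)
})

test_that("identical seeds give bit-identical tallies", {
  a <- run_scenario(quick_scenario(660, "moderate", mode = "reflectance",
                                   sds = 3, n_photons = 8e3, seed = 5L))
  b <- run_scenario(quick_scenario(660, "moderate", mode = "reflectance",
                                   sds = 3, n_photons = 8e3, seed = 5L))
  expect_identical(glance(a), glance(b))
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$absorbed, b$absorbed)

  c <- run_scenario(quick_scenario(660, "moderate", mode = "reflectance",
                                   sds = 3, n_photons = 8e3, seed = 6L))
  expect_false(identical(a$w_detected, c$w_detected))
})

test_that("empty launches produce empty tallies", {
  t <- run_scenario(quick_scenario(n_photons = 0))
  expect_identical(t$n_detected, 0)
  expect_identical(t$w_detected, 0)
  expect_identical(sum(t$absorbed), 0)
  expect_identical(nrow(tidy(t)), 0L)
})

test_that("transmittance-detected photons traversed the whole finger", {
  t <- run_scenario(quick_scenario(940, "light", n_photons = 4e4))
  expect_gt(t$n_detected, 0)
  expect_true(all(abs(t$records$z_max - 13.0) < 1e-9))
  expect_true(all(t$records$pathlength >= 13.0))
  expect_true(all(t$records$w > 0 & t$records$w <= 1))
})

test_that("implicit capture multiplies the weight by the albedo per event", {
  # forward-scattering slab: every photon exits with weight albedo^k
  slab <- homogeneous_slab(mua = 1, mus = 1, g = 1, thickness = 2)
  t <- run_transport(slab, 2000, seed = 13, detector_radius = 1000,
                     lateral_max = 1e4, roulette_threshold = 1e-30)
  k <- log(t$records$w) / log(0.5)
  expect_true(all(abs(k - round(k)) < 1e-9))
  expect_gt(max(k), 0)
})

test_that("reflectance photons stay shallower than transmittance photons", {
  refl <- run_scenario(quick_scenario(940, "light", mode = "reflectance",
                                      sds = 1, n_photons = 2e4))
  trans <- run_scenario(quick_scenario(940, "light", n_photons = 2e4))
  expect_gt(trans$n_detected, 0)
  expect_gt(refl$n_detected, 0)
  expect_lt(mean(refl$records$z_max), mean(trans$records$z_max))
})

test_that("detected counts fall as source-detector separation grows", {
  counts <- vapply(c(1, 5, 9), function(s) {
    run_scenario(quick_scenario(940, "light", mode = "reflectance",
                                sds = s, n_photons = 3e4, seed = 50L)
    )$n_detected
  }, numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("detected counts fall as melanin concentration rises", {
  counts <- vapply(c("light", "moderate", "dark"), function(st) {
    run_scenario(quick_scenario(660, st, mode = "reflectance", sds = 1,
                                n_photons = 2e4, seed = 60L))$n_detected
  }, numeric(1))
  expect_true(all(diff(counts) < 0))
})
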