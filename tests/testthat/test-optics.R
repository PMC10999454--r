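test_that("property table round-trips every tabulated optical coefficient", {
  expected <- table2_cells()
  tbl <- tissue_properties()
  for (i in seq_len(nrow(expected))) {
    row <- tbl[tbl$tissue == expected$tissue[i] &
                 tbl$wavelength == expected$wavelength[i], ]
    expect_equal(nrow(row), 1)
    for (col in c("mua", "mus", "g")) {
      if (is.na(expected[[col]][i])) next
      expect_identical(row[[col]], expected[[col]][i],
                       label = paste(expected$tissue[i], col))
    }
  }
  expect_error(tissue_properties(550), class = "fingerppg_missing_property")
})

test_that("melanin absorption follows the printed power law", {
  expect_equal(melanin_mua(660), 26.94, tolerance = 5e-4)
  expect_equal(melanin_mua(940), 8.299, tolerance = 5e-4)
  # strictly decreasing in wavelength
  wl <- seq(400, 1000, by = 50)
  expect_true(all(diff(melanin_mua(wl)) < 0))
  expect_error(melanin_mua(-1), class = "fingerppg_invalid_parameter")
})

test_that("epidermal absorption reproduces the published six-cell table", {
  presets <- skin_presets()
  expected <- tibble::tribble(
    ~skin_type, ~wavelength, ~mua,  ~tol,
    "light",            660, 0.727, 0.06,
    "moderate",         660, 4.21,  0.01,
    "dark",             660, 8.24,  0.01,
    "light",            940, 0.229, 0.06,
    "moderate",         940, 1.30,  0.01,
    "dark",             940, 2.54,  0.01
  )
  for (i in seq_len(nrow(expected))) {
    v <- presets$v_mel[presets$skin_type == expected$skin_type[i]]
    got <- epidermis_mua(v, expected$wavelength[i])
    expect_lt(abs(got - expected$mua[i]) / expected$mua[i], expected$tol[i])
    # melanin contribution is a lower bound
    expect_gte(got, v * melanin_mua(expected$wavelength[i]))
  }
})

test_that("epidermal absorption is strictly increasing in melanin fraction", {
  for (wl in c(660, 940)) {
    v <- seq(0, 0.35, by = 0.05)
    expect_true(all(diff(epidermis_mua(v, wl)) > 0))
  }
})

test_that("dark/light epidermal absorption ratio is about elevenfold", {
  for (wl in c(660, 940)) {
    ratio <- epidermis_mua(0.305, wl) / epidermis_mua(0.0255, wl)
    expect_gte(ratio, 10)
    expect_lte(ratio, 12)
  }
})

test_that("chromophore-free epidermis reduces to the baseline term", {
  for (wl in c(660, 940)) {
    expect_identical(epidermis_mua(0, wl, v_water = 0, mua_water = 0),
                     baseline_mua(wl))
  }
  expect_error(epidermis_mua(0.6, 660, v_water = 0.6),
               class = "fingerppg_invalid_parameter")
  expect_error(epidermis_mua(-0.1, 660),
               class = "fingerppg_invalid_parameter")
})

test_that("blood absorption mixes haemoglobin species by saturation", {
  expect_identical(blood_mua(660, 1), 0.15)
  expect_identical(blood_mua(940, 1), 0.65)
  expect_identical(blood_mua(660, 0), 1.64)
  expect_equal(blood_mua(940, 0.5), 0.5 * 0.65 + 0.5 * 0.43)
  expect_error(blood_mua(800, 1), class = "fingerppg_missing_property")
  expect_error(blood_mua(660, 1.2), class = "fingerppg_invalid_parameter")
})

test_that("dermal absorption follows the nested blood/water/baseline mix", {
  row <- tibble::tibble(sublayer = "papillary_dermis",
                        v_blood_diastole = 0.05, v_water = 0.5)
  # frozen hand evaluation of the mixing sum at 940 nm, diastole
  expected <- 0.05 * 0.65 +
    0.95 * (0.5 * 0.02674 + 0.5 * baseline_mua(940))
  expect_equal(dermal_mua(row, "diastole", 940), expected)

  # systole doubles the blood volume and raises absorption
  for (i in 3:6) {
    sub <- skin_sublayers()[i, ]
    for (wl in c(660, 940)) {
      expect_gt(dermal_mua(sub, "systole", wl),
                dermal_mua(sub, "diastole", wl))
    }
  }

  # no blood means no phase dependence
  dry <- tibble::tibble(sublayer = "reticular_dermis",
                        v_blood_diastole = 0, v_water = 0.65)
  expect_identical(dermal_mua(dry, "systole", 660),
                   dermal_mua(dry, "diastole", 660))

  expect_error(dermal_mua(skin_sublayers()[2, ], "diastole", 660),
               class = "fingerppg_invalid_parameter")
  over <- tibble::tibble(sublayer = "deep_blood_net",
                         v_blood_diastole = 0.6, v_water = 0.2)
  expect_error(dermal_mua(over, "systole", 660),
               class = "fingerppg_invalid_model")
})

test_that("property-table export resolves the epidermis presets", {
  tbl <- export_property_table()
  expect_true(all(c("tissue", "wavelength_nm", "mua_mm", "mus_mm", "g",
                    "n") %in% names(tbl)))
  epi <- tbl[tbl$tissue == "epidermis_dark" & tbl$wavelength_nm == 940, ]
  expect_equal(epi$mua_mm, epidermis_mua(0.305, 940))
  expect_equal(epi$mus_mm, 15.68)

  path <- withr::local_tempfile(fileext = ".csv")
  export_property_table(path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(tbl))
  expect_equal(back$mua_mm[back$tissue == "melanin" &
                             back$wavelength_nm == 660], 26.94)
})

test_that("stratum corneum first-step thresholds match the published values", {
  expect_equal(first_step_crossing_probability(sc_mu_t(660), 0.02),
               0.5985, tolerance = 1e-3)
  expect_equal(first_step_crossing_probability(sc_mu_t(940), 0.02),
               0.7306, tolerance = 1e-3)
  # transparent layer passes every deviate
  expect_equal(first_step_crossing_probability(1e-12, 0.02), 1,
               tolerance = 1e-9)
})
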