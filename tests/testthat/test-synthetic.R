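test_that("noiseless standard series reproduces the linear response exactly", {
  # mass 0.2 ug of the internal reference on UPLC: area = k*m + b
  tab <- simulate_standard_series(
    concentrations_ug_mL = c(C3 = 1000), volumes_uL = 0.2,
    noise = no_noise(), seed = 1)
  expect_equal(tab$area, 19503.76 * 0.2 - 50.67, tolerance = 1e-12)
  expect_equal(tab$area, 3850.082, tolerance = 1e-9)
  expect_equal(tab$injected_mass_ug, 0.2)

  # zero mass with zero intercept gives zero area
  rm0 <- intercept_free_response()
  tab0 <- simulate_standard_series(response = rm0,
                                   concentrations_ug_mL = c(C3 = 1e-9),
                                   volumes_uL = 0.2, noise = no_noise(),
                                   check_range = FALSE)
  expect_equal(tab0$area, 19503.76 * 0.2e-12, tolerance = 1e-15)
})

test_that("standard series emits one record per component per level", {
  tab <- simulate_standard_series(noise = no_noise())
  expect_identical(nrow(tab), 30L)  # 6 volumes x 5 components
  expect_true(all(table(tab$component_code) == 6))
  expect_false(anyNA(tab$injected_mass_ug))
})

test_that("generators are deterministic in the seed", {
  a <- simulate_standard_series(seed = 42)
  b <- simulate_standard_series(seed = 42)
  c <- simulate_standard_series(seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))

  s1 <- simulate_sample_table(seed = 7)
  s2 <- simulate_sample_table(seed = 7)
  expect_identical(s1, s2)
})

test_that("sample simulation converts contents to injected masses correctly", {
  # 1.073 mg/g, 4 g / 20 mL, 0.5 uL -> 0.1073 ug -> area k*m + b
  prof <- data.frame(sample_id = "s", component_code = "C3",
                     content_mg_g = 1.073)
  tab <- simulate_sample_table(prof, system = uplc_reference_system(),
                               noise = no_noise(), n_replicates = 1L,
                               label_components = TRUE)
  expect_equal(tab$area, 19503.76 * 0.1073 - 50.67, tolerance = 1e-10)
  expect_true(is.na(tab$injected_mass_ug))  # unknowns carry no mass

  # zero content: only the intercept remains (positive-intercept system)
  prof0 <- data.frame(sample_id = "s", component_code = "C3",
                      content_mg_g = 0)
  tab0 <- simulate_sample_table(prof0, system = hplc_reference_system(),
                                noise = no_noise(), n_replicates = 1L)
  expect_equal(tab0$area, 80.52, tolerance = 1e-12)
})

test_that("replicate injections get distinct ids that strip back to the sample", {
  tab <- simulate_sample_table(one_region_profile(), n_replicates = 3L,
                               noise = no_noise())
  expect_identical(nrow(tab), 15L)
  expect_setequal(unique(strip_replicate_suffix(tab$sample_id)), "Beihai")
  expect_identical(anyDuplicated(paste(tab$sample_id, tab$retention_time_min)), 0L)
})

test_that("area noise at a requested RSD produces matching empirical RSDs", {
  prof <- do.call(rbind, lapply(1:200, function(i)
    data.frame(sample_id = sprintf("p%03d", i), component_code = "C3",
               content_mg_g = 1.5)))
  tab <- simulate_sample_table(prof, noise = noise_model(1.0, 0),
                               n_replicates = 1L, seed = 99,
                               label_components = TRUE)
  emp <- rsd(tab$area)
  # sd of an RSD estimate is ~ rsd/sqrt(2 n); allow 3 standard errors
  expect_lt(abs(emp - 1.0), 3 * 1.0 / sqrt(2 * 200))
})

test_that("retention structure follows the relative-retention model", {
  tab <- simulate_sample_table(one_region_profile(), noise = no_noise(),
                               n_replicates = 1L, label_components = TRUE)
  rt_s <- tab$retention_time_min[tab$component_code == "C3"]
  rrt <- tab$retention_time_min / rt_s
  expected <- default_rrt_table()
  expected <- expected[expected$instrument_class == "UPLC", ]
  expect_equal(rrt[match(expected$component_code, tab$component_code)],
               expected$rrt, tolerance = 1e-12)
})

test_that("simulators reject invalid arguments", {
  expect_error(simulate_standard_series(volumes_uL = -1), "positive")
  expect_error(extraction_spec(sample_mass_g = 0), "positive")
  expect_error(noise_model(area_rsd = -1), "non-negative")
  prof <- data.frame(sample_id = "s", component_code = "C3",
                     content_mg_g = -1)
  expect_error(simulate_sample_table(prof), "content_mg_g")
})

test_that("masses outside the stated linear range are warned about", {
  expect_warning(
    simulate_standard_series(concentrations_ug_mL = c(C3 = 1000),
                             volumes_uL = 1.0, noise = no_noise()),
    "outside linear range")
})
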