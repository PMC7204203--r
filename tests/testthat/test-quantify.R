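test_that("QAMS mass formulas follow their defining arithmetic", {
  expect_equal(quantify_qams1(300, 600, 0.2, 0.25), 0.4)
  expect_equal(quantify_qams1(500, 500, 0.3, 1), 0.3)
  f <- slope_rcf(7794.28, 19503.76)
  expect_equal(quantify_qams2(100, 19503.76, f), 100 / 7794.28,
               tolerance = 1e-12)
  expect_equal(quantify_qams2(100, 19503.76, f), 0.012830, tolerance = 1e-4)
  expect_error(quantify_qams1(1, 0, 1, 1), "positive")
  expect_error(quantify_qams2(1, -2, 1), "positive")
})

test_that("content conversion is the exact inverse of the generator's forward step", {
  ex <- extraction_spec(4, 20)
  expect_equal(to_content(0.1073, 0.5, ex), 1.073, tolerance = 1e-12)
  expect_equal(to_content(0, 0.5, ex), 0)
  expect_equal(to_content(0.1073, 0.5, extraction_spec(4, 40)),
               2 * 1.073, tolerance = 1e-12)
  # round trip: content -> injected mass (generator rule) -> content
  content <- 2.438
  m <- content * ex$sample_mass_g / ex$extract_volume_mL * 0.5
  expect_equal(to_content(m, 0.5, ex), content, tolerance = 1e-12)
})

test_that("ESM delegates to the analyte's own curve and rejects mismatches", {
  std <- simulate_standard_series(noise = no_noise())
  curves <- fit_calibrations(std)
  area <- 19503.76 * 0.1073 - 50.67
  expect_equal(as.numeric(quantify_esm(area, curves$C3, "C3")), 0.1073,
               tolerance = 1e-9)
  expect_equal(as.numeric(quantify_esm(curves$C3$intercept, curves$C3)), 0,
               tolerance = 1e-9)
  expect_error(quantify_esm(100, curves$C3, "C1"), "not C1")
})

test_that("all three methods agree to machine precision without intercepts or noise", {
  resp <- intercept_free_response()
  std <- simulate_standard_series(response = resp, noise = no_noise())
  curves <- fit_calibrations(std)
  mp <- multipoint_rcf_table(std)
  mp_f <- stats::setNames(mp$summary$mean, mp$summary$component_code)
  sf <- slope_rcf_set(curves)

  tab <- simulate_sample_table(response = resp, noise = no_noise(),
                               n_replicates = 1L, label_components = TRUE)
  q <- quantify_samples(tab, curves, multipoint_f = mp_f, slope_f = sf)
  wide <- split(q, q$method)
  key <- function(d) d[order(d$sample_id, d$component_code), "content_mg_g"]
  expect_equal(key(wide$ESM), key(wide$QAMS1), tolerance = 1e-12)
  expect_equal(key(wide$ESM), key(wide$QAMS2), tolerance = 1e-12)

  # and they all recover the generating contents exactly
  truth <- default_content_profile()
  truth <- truth[order(truth$sample_id, truth$component_code), ]
  expect_equal(key(wide$ESM), truth$content_mg_g, tolerance = 1e-10)
})

test_that("QAMS2 - ESM is the constant intercept offset per component", {
  std <- simulate_standard_series(noise = no_noise())
  curves <- fit_calibrations(std)
  sf <- slope_rcf_set(curves)
  tab <- simulate_sample_table(noise = no_noise(), n_replicates = 1L,
                               label_components = TRUE)
  q <- quantify_samples(tab, curves, slope_f = sf,
                        methods = c("ESM", "QAMS2"))
  ex <- extraction_spec()
  for (code in paste0("C", 1:5)) {
    esm <- q[q$method == "ESM" & q$component_code == code, ]
    q2 <- q[q$method == "QAMS2" & q$component_code == code, ]
    q2 <- q2[match(esm$sample_id, q2$sample_id), ]
    delta <- q2$content_mg_g - esm$content_mg_g
    expect_lt(diff(range(delta)), 1e-10)  # constant across samples
    expected <- curves[[code]]$intercept / curves[[code]]$slope *
      ex$extract_volume_mL / (0.5 * ex$sample_mass_g)
    expect_equal(mean(delta), expected, tolerance = 1e-9)
  }
})

test_that("replicate injections are averaged into one row per sample", {
  tab <- simulate_sample_table(one_region_profile(),
                               noise = noise_model(0.3, 0.02),
                               n_replicates = 3L, label_components = TRUE)
  std <- simulate_standard_series(noise = no_noise())
  curves <- fit_calibrations(std)
  q <- quantify_samples(tab, curves, methods = "ESM")
  expect_identical(nrow(q), 5L)
  expect_setequal(q$sample_id, "Beihai")
  q_raw <- quantify_samples(tab, curves, methods = "ESM",
                            average_replicates = FALSE)
  expect_identical(nrow(q_raw), 15L)
  mean_c3 <- mean(q_raw$content_mg_g[q_raw$component_code == "C3"])
  expect_equal(q$content_mg_g[q$component_code == "C3"], mean_c3,
               tolerance = 1e-12)
})

test_that("missing prerequisites give named errors", {
  std <- simulate_standard_series(noise = no_noise())
  curves <- fit_calibrations(std)
  tab <- simulate_sample_table(one_region_profile(), noise = no_noise(),
                               n_replicates = 1L, label_components = TRUE)
  expect_error(quantify_samples(tab, curves, methods = "QAMS1"),
               "multipoint_f")
  expect_error(quantify_samples(tab, curves, methods = "QAMS2"),
               "slope_f")
  expect_error(quantify_samples(tab, curves["C1"], methods = "QAMS2",
                                slope_f = c(C1 = 0.4)),
               "internal reference")
  unassigned <- tab
  unassigned$component_code <- NA_character_
  expect_error(quantify_samples(unassigned, curves), "no assigned peaks")
})
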