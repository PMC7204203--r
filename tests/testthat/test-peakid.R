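test_that("relative retention is the plain ratio and rejects bad inputs", {
  expect_equal(relative_retention(5, 5), 1.0)
  expect_equal(relative_retention(2.5, 5), 0.5)
  expect_equal(relative_retention(11 * 1.179, 11), 1.179, tolerance = 1e-12)
  expect_error(relative_retention(-1, 5), "positive")
})

test_that("RRT is invariant under uniform time scaling", {
  rt <- c(5.9, 9.1, 11, 11.7, 13)
  for (c_scale in c(0.5, 2.4, 10))
    expect_equal(relative_retention(c_scale * rt, c_scale * rt[3]),
                 relative_retention(rt, rt[3]), tolerance = 1e-14)
})

test_that("a clean five-peak table is fully and correctly assigned", {
  tab <- simulate_sample_table(one_region_profile(), noise = no_noise(),
                               n_replicates = 1L)
  asg <- assign_peaks(tab, default_rrt_reference("UPLC"))
  expect_setequal(asg$component_code, paste0("C", 1:5))
  # codes land on the right retention times
  truth <- simulate_sample_table(one_region_profile(), noise = no_noise(),
                                 n_replicates = 1L, label_components = TRUE)
  m <- match(asg$retention_time_min, truth$retention_time_min)
  expect_identical(asg$component_code, truth$component_code[m])
  rep <- attr(asg, "assignment")
  expect_true(all(rep$status == "assigned"))
})

test_that("assignment is permutation-invariant to row order", {
  tab <- simulate_sample_table(one_region_profile(),
                               noise = noise_model(0.3, 0.02),
                               n_replicates = 1L, seed = 5)
  shuf <- tab[c(4, 1, 5, 3, 2), ]
  a1 <- assign_peaks(tab, default_rrt_reference("UPLC"))
  a2 <- assign_peaks(shuf, default_rrt_reference("UPLC"))
  key1 <- a1$component_code[order(a1$retention_time_min)]
  key2 <- a2$component_code[order(a2$retention_time_min)]
  expect_identical(key1, key2)
})

test_that("a missing component is reported absent without disturbing the rest", {
  tab <- simulate_sample_table(one_region_profile(), noise = no_noise(),
                               n_replicates = 1L, label_components = TRUE)
  tab <- peak_table(tab[tab$component_code != "C2", ])
  tab$component_code <- NA_character_
  asg <- assign_peaks(tab, default_rrt_reference("UPLC"))
  rep <- attr(asg, "assignment")
  expect_identical(rep$status[rep$component_code == "C2"], "absent")
  expect_setequal(asg$component_code, c("C1", "C3", "C4", "C5"))
})

test_that("two candidate peaks for one expected RRT is an ambiguity error", {
  tab <- peak_table(data.frame(
    sample_id = "s", system_id = "UPLC", component_code = NA_character_,
    retention_time_min = c(10, 10 * 1.06, 10 * 1.07),
    area = c(1000, 400, 500), injection_volume_uL = 0.5,
    injected_mass_ug = NA_real_))
  ref <- rrt_reference(c(C4 = 1.07), tolerance = 0.02)
  expect_error(assign_peaks(tab, ref, internal_rt_hint_min = 10),
               "ambiguous")
})

test_that("the reference-peak hint restricts the search window", {
  tab <- simulate_sample_table(one_region_profile(), noise = no_noise(),
                               n_replicates = 1L)
  asg <- assign_peaks(tab, default_rrt_reference("UPLC"),
                      internal_rt_hint_min = 11)
  expect_setequal(asg$component_code, paste0("C", 1:5))
  expect_error(assign_peaks(tab, default_rrt_reference("UPLC"),
                            internal_rt_hint_min = 50),
               "no internal-reference candidate")
})

test_that("assignment stays perfect over many seeds at realistic rt jitter", {
  # independent per-peak jitter of 0.3% of the reference rt (the scale of
  # routine run-to-run rt precision); the +/-2% window then sits >4 sd
  # from the nearest wrong match
  ref <- default_rrt_reference("UPLC")
  n_bad <- 0L
  for (seed in 1:400) {
    tab <- simulate_sample_table(one_region_profile(),
                                 noise = noise_model(0, 0.033),
                                 n_replicates = 1L, seed = seed)
    truth <- simulate_sample_table(one_region_profile(),
                                   noise = noise_model(0, 0.033),
                                   n_replicates = 1L, seed = seed,
                                   label_components = TRUE)
    asg <- try(assign_peaks(tab, ref), silent = TRUE)
    ok <- !inherits(asg, "try-error") &&
      identical(asg$component_code, truth$component_code)
    if (!ok) n_bad <- n_bad + 1L
  }
  expect_identical(n_bad, 0L)
})
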