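test_that("multipoint RCF arithmetic is exactly (m_s A_i)/(m_i A_s)", {
  expect_equal(multipoint_rcf(1, 10, 1, 10), 1.0)
  expect_equal(multipoint_rcf(2, 6, 4, 3), 0.25)
  expect_error(multipoint_rcf(0, 1, 1, 1), "positive")
  expect_error(multipoint_rcf(1, 1, -2, 1), "positive")
})

test_that("multipoint RCF is invariant to detector gain and mass rescaling", {
  withr::with_seed(4, {
    m_s <- runif(20, 0.1, 0.4); A_s <- runif(20, 1e3, 1e4)
    m_i <- runif(20, 0.01, 0.1); A_i <- runif(20, 1e2, 1e3)
  })
  f <- multipoint_rcf(m_s, A_s, m_i, A_i)
  expect_equal(multipoint_rcf(m_s, 7 * A_s, m_i, 7 * A_i), f, tolerance = 1e-14)
  expect_equal(multipoint_rcf(3 * m_s, A_s, 3 * m_i, A_i), f, tolerance = 1e-14)
})

test_that("slope RCFs from the reference slopes reproduce the reported values", {
  expect_equal(round_half_up(slope_rcf(7794.28, 19503.76), 3), 0.400)
  expect_equal(round_half_up(slope_rcf(3249.11, 3574.23), 3), 0.909)
  expect_equal(slope_rcf(5, 5), 1.0)
  expect_error(slope_rcf(-1, 2), "positive")
})

test_that("multipoint equals slope RCF at every level when intercepts and noise vanish", {
  std <- simulate_standard_series(response = intercept_free_response(),
                                  noise = no_noise())
  mp <- multipoint_rcf_table(std)
  sf <- slope_rcf_set(fit_calibrations(std))
  for (code in names(sf)) {
    per <- mp$per_level$f[mp$per_level$component_code == code]
    expect_true(all(abs(per - sf[[code]]) < 1e-12), info = code)
  }
})

test_that("with intercepts, multipoint values drift with level toward the slope ratio", {
  std <- simulate_standard_series(noise = no_noise())
  mp <- multipoint_rcf_table(std)
  sf <- slope_rcf_set(fit_calibrations(std))
  for (code in names(sf)) {
    d <- mp$per_level[mp$per_level$component_code == code, ]
    d <- d[order(d$injection_volume_uL), ]
    dev <- abs(d$f - sf[[code]])
    # the intercept bias shrinks as injected mass grows
    expect_lt(dev[nrow(d)], dev[1])
  }
})

test_that("aggregation reproduces the reported per-volume means", {
  ref <- reference_multipoint_rcfs()
  u_c2 <- ref$f[ref$system_id == "UPLC" & ref$component_code == "C2"]
  h_c4 <- ref$f[ref$system_id == "HPLC" & ref$component_code == "C4"]
  expect_equal(round_half_up(aggregate_multipoint(u_c2)$mean, 3), 0.486)
  expect_equal(round_half_up(aggregate_multipoint(h_c4)$mean, 3), 0.798)
  expect_equal(aggregate_multipoint(rep(0.4, 5))$rsd_percent, 0)
  expect_error(aggregate_multipoint(0.4), ">= 2")
})

test_that("robustness summary computes per-analyte cross-condition RSDs", {
  rob <- robustness_summary(reference_rcf_robustness())
  c1 <- rob$rsd_percent[rob$component_code == "C1"]
  expect_equal(c1, 2.270, tolerance = 0.001)
  expect_true(all(rob$rsd_percent <= 2.28))

  same <- data.frame(condition = c("a", "b"), C1 = c(0.4, 0.4))
  expect_equal(robustness_summary(same)$rsd_percent, 0)
  wider <- data.frame(condition = c("a", "b"), C1 = c(0.4, 0.5))
  expect_gt(robustness_summary(wider)$rsd_percent,
            robustness_summary(same)$rsd_percent)
  expect_error(robustness_summary(list(c(C1 = 0.4), c(C2 = 0.4))),
               "panels differ")
})

test_that("flavone analytes sit nearer unity than the structurally distant ones", {
  # luteolin/kaempferol differ from quercetin only in hydroxylation, so
  # their f is close to 1; the glycoside and the gallate sit near 0.5/0.4
  sf <- slope_rcf_set(fit_calibrations(
    simulate_standard_series(noise = no_noise())))
  expect_true(all(abs(sf[c("C4", "C5")] - 1) < abs(sf[c("C1", "C2")] - 1)))
})
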