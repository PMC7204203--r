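test_that("panel validation enforces a single internal reference and unique codes", {
  expect_silent(validate_panel(longan_panel()))
  expect_identical(internal_reference_code(longan_panel()), "C3")

  none <- longan_panel()
  none$is_internal_reference <- FALSE
  expect_error(validate_panel(none), "exactly one internal reference")

  two <- longan_panel()
  two$is_internal_reference[c(3, 5)] <- TRUE
  expect_error(validate_panel(two), "exactly one internal reference")

  dup <- longan_panel()
  dup$code[5] <- "C3"
  expect_error(validate_panel(dup), "duplicate")
})

test_that("peak-table CSV write -> read is the identity on all fields", {
  for (seed in 1:5) {
    tab <- peak_table(random_peak_table(seed))
    path <- withr::local_tempfile(fileext = ".csv")
    write_peak_table(tab, path)
    back <- read_peak_table(path)
    expect_equal(as.data.frame(back), as.data.frame(tab),
                 tolerance = 0, info = paste("seed", seed))
  }
  # empty table round-trips to a header-only file
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(peak_table(), path)
  expect_identical(length(readLines(path)), 1L)
  expect_identical(nrow(read_peak_table(path)), 0L)
})

test_that("absent injected mass survives the round trip as NA, distinct from 0", {
  tab <- random_peak_table(11)
  tab$injected_mass_ug <- c(0, NA_real_, rep(1.5, nrow(tab) - 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(peak_table(tab), path)
  back <- read_peak_table(path)
  expect_identical(back$injected_mass_ug[1], 0)
  expect_true(is.na(back$injected_mass_ug[2]))
})

test_that("malformed peak-table files fail with informative errors", {
  tab <- random_peak_table(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(peak_table(tab), path)

  lines <- readLines(path)
  # drop the area column
  noarea <- vapply(strsplit(lines, ","), function(x) paste(x[-5], collapse = ","), "")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(noarea, p2)
  expect_error(read_peak_table(p2), "area")

  # a comma decimal mark leaves a stray field; quote it to keep the column
  # count and check the row-level error names the line
  broken <- lines
  broken[3] <- sub("^(([^,]*,){4})([0-9.]+)", "\\1\"1,5\"", broken[3])
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(broken, p3)
  expect_error(read_peak_table(p3), "line 2")

  expect_error(read_peak_table(withr::local_tempfile()), "no such file")
})

test_that("peak-table invariants reject bad rows and duplicate keys", {
  tab <- random_peak_table(5)
  bad <- tab; bad$retention_time_min[1] <- -1
  expect_error(peak_table(bad), "retention_time")
  bad <- tab; bad$area[2] <- -5
  expect_error(peak_table(bad), "area")
  dup <- rbind(tab, tab[1, ])
  expect_error(peak_table(dup), "duplicate")
})

test_that("system configuration round-trips through YAML", {
  systems <- list(UPLC = uplc_reference_system(),
                  HPLC = hplc_reference_system())
  path <- withr::local_tempfile(fileext = ".yaml")
  write_system_config(systems, path)
  back <- read_system_config(path)
  expect_identical(names(back), c("UPLC", "HPLC"))
  expect_equal(back$UPLC$gradient, systems$UPLC$gradient)
  expect_equal(back$HPLC$flow_rate_mL_min, 1.0)
  expect_equal(back$UPLC$injection_volume_uL, 0.5)
})

test_that("gradient validation rejects broken programs", {
  g <- uplc_reference_system()$gradient
  bad <- g; bad$t_end_min[1] <- 0
  expect_error(chrom_system("x", "UPLC", column_inner_diameter_mm = 2.1,
                            column_length_mm = 100, flow_rate_mL_min = 0.2,
                            injection_volume_uL = 0.5, gradient = bad),
               "t_end > t_start")
  bad <- g; bad$percent_A_end[3] <- 120
  expect_error(validate_gradient(bad), "0, 100")
  bad <- g; bad$t_start_min[1] <- 1
  expect_error(validate_gradient(bad), "start at t = 0")
})
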