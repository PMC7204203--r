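# Shared fixtures: noiseless / intercept-free model variants and a small
# random peak-table generator for round-trip properties.

no_noise <- function() noise_model(0, 0)

intercept_free_response <- function() {
  tab <- reference_calibrations()
  tab$intercept <- 0
  response_model(tab)
}

random_peak_table <- function(seed, n = 8) {
  withr::with_seed(seed, {
    data.frame(
      sample_id = sample(c("a", "b", "c"), n, replace = TRUE),
      system_id = "UPLC",
      component_code = ifelse(stats::runif(n) < 0.3, NA_character_,
                              sample(paste0("C", 1:5), n, replace = TRUE)),
      retention_time_min = sort(stats::runif(n, 0.5, 20)),
      area = stats::runif(n, 0, 5e4),
      injection_volume_uL = sample(c(0.5, 5), n, replace = TRUE),
      injected_mass_ug = ifelse(stats::runif(n) < 0.5, NA_real_,
                                stats::runif(n, 0, 2)),
      stringsAsFactors = FALSE)
  })
}

# one-region content profile for compact harnesses
one_region_profile <- function(region = "Beihai") {
  prof <- default_content_profile()
  prof[prof$sample_id == region, ]
}
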