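# Seeded synthetic generator: standard-series and sample peak tables with
# the statistical structure the analysis assumes (linear detector
# response, relative-retention-time structure, multiplicative area noise),
# so every downstream stage is testable without an instrument.

#' Detector response model
#'
#' Linear per-(component, system) response `area = slope * mass_ug +
#' intercept`. Defaults are the reference calibration constants of the
#' longan-leaf assay.
#'
#' @param table data frame with columns `component_code`, `system_id`,
#'   `slope`, `intercept` (optionally `range_min_ug`, `range_max_ug`).
#' @return A `response_model` data frame.
#' @export
response_model <- function(table = reference_calibrations()) {
  stopifnot(is.data.frame(table),
            all(c("component_code", "system_id", "slope", "intercept")
                %in% names(table)))
  if (any(table$slope <= 0)) stop("slopes must be positive", call. = FALSE)
  class(table) <- unique(c("response_model", class(table)))
  table
}

response_for <- function(response, component_code, system_id) {
  row <- response[response$component_code == component_code &
                  response$system_id == system_id, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("response model has no unique entry for ", component_code, " on ",
         system_id, call. = FALSE)
  row
}

#' Measurement noise model
#'
#' Areas receive multiplicative normal noise with standard deviation
#' `area_rsd` percent of the mean (truncated at 0); retention times
#' receive additive normal jitter with standard deviation `rt_jitter_sd`
#' minutes. Defaults follow the instrument-precision scale of the
#' reference assay: six repeated injections gave area RSDs of roughly
#' 0.2-0.4 % on UPLC and 0.7-2 % on HPLC.
#'
#' @param area_rsd percent RSD of the multiplicative area noise.
#' @param rt_jitter_sd retention-time jitter sd, minutes.
#' @return A `noise_model` list.
#' @export
noise_model <- function(area_rsd = 0.3, rt_jitter_sd = 0.02) {
  stop_if_not_positive(area_rsd = area_rsd, rt_jitter_sd = rt_jitter_sd,
                       .allow_zero = TRUE)
  structure(list(area_rsd = area_rsd, rt_jitter_sd = rt_jitter_sd),
            class = "noise_model")
}

#' @param instrument_class `"UPLC"` or `"HPLC"`.
#' @rdname noise_model
#' @export
default_noise_model <- function(instrument_class = c("UPLC", "HPLC")) {
  instrument_class <- match.arg(instrument_class)
  if (instrument_class == "UPLC") noise_model(0.3, 0.02)
  else noise_model(1.0, 0.08)
}

noisy_area <- function(mean_area, noise) {
  if (noise$area_rsd == 0) return(mean_area)
  pmax(0, mean_area * (1 + stats::rnorm(length(mean_area),
                                        sd = noise$area_rsd / 100)))
}

noisy_rt <- function(rt, noise) {
  if (noise$rt_jitter_sd == 0) return(rt)
  rt + stats::rnorm(length(rt), sd = noise$rt_jitter_sd)
}

#' Retention model
#'
#' Retention is simulated directly from relative-retention structure: the
#' internal reference elutes at an absolute time per instrument class and
#' every other component at its relative retention times that time. The
#' reference assay prints no absolute retention times, so the defaults
#' (11 min UPLC, 26 min HPLC) are chosen to place all five peaks inside
#' the printed gradient windows with the detection-wavelength switch
#' falling between the first and second peak.
#'
#' @param internal_rt_min named numeric, internal-reference retention time
#'   (min) per instrument class.
#' @param rrt data frame `instrument_class`, `component_code`, `rrt`
#'   (relative retention; 1 for the internal reference). Defaults are the
#'   per-class means of the reference relative-retention table.
#' @return A `retention_model` list.
#' @export
retention_model <- function(internal_rt_min = c(UPLC = 11, HPLC = 26),
                            rrt = default_rrt_table()) {
  stop_if_not_positive(internal_rt_min = internal_rt_min)
  stopifnot(all(c("instrument_class", "component_code", "rrt") %in% names(rrt)),
            all(rrt$rrt > 0))
  structure(list(internal_rt_min = internal_rt_min, rrt = rrt),
            class = "retention_model")
}

default_rrt_table <- function() {
  ref <- reference_rrt()
  codes <- c("C1", "C2", "C4", "C5")
  per_class <- do.call(rbind, lapply(c("UPLC", "HPLC"), function(cl) {
    m <- colMeans(ref[ref$instrument_class == cl, codes])
    data.frame(instrument_class = cl,
               component_code = c(codes, "C3"), rrt = c(unname(m), 1),
               stringsAsFactors = FALSE)
  }))
  per_class
}

retention_for <- function(retention, component_code, instrument_class) {
  base <- retention$internal_rt_min[[instrument_class]]
  if (is.null(base)) stop("no internal-reference retention time for class ",
                          instrument_class, call. = FALSE)
  tab <- retention$rrt
  r <- tab$rrt[tab$instrument_class == instrument_class &
               tab$component_code == component_code]
  if (length(r) != 1L)
    stop("no relative retention for ", component_code, " on ",
         instrument_class, call. = FALSE)
  base * r
}

#' Extraction parameters
#'
#' Mass of dry leaf powder extracted into a fixed final volume; contents
#' in mg/g convert to extract concentrations through these. Defaults are
#' the reference assay's 4.0 g into 20 mL.
#'
#' @param sample_mass_g powder mass, g.
#' @param extract_volume_mL final extract volume, mL.
#' @return An `extraction_spec` list.
#' @export
extraction_spec <- function(sample_mass_g = 4.0, extract_volume_mL = 20) {
  stop_if_not_positive(sample_mass_g = sample_mass_g,
                       extract_volume_mL = extract_volume_mL)
  structure(list(sample_mass_g = sample_mass_g,
                 extract_volume_mL = extract_volume_mL),
            class = "extraction_spec")
}

#' Default regional content profile
#'
#' True per-region, per-component contents (mg/g) used by the sample
#' simulator; defaults to the reference UPLC determinations for the ten
#' Guangxi growing regions.
#'
#' @return Data frame: `sample_id`, `component_code`, `content_mg_g`.
#' @export
default_content_profile <- function() {
  ref <- reference_contents()
  ref <- ref[ref$system_id == "UPLC", ]
  data.frame(sample_id = ref$region, component_code = ref$component_code,
             content_mg_g = ref$content_mg_g, stringsAsFactors = FALSE)
}

#' Simulate a calibration standard series
#'
#' Emulates injecting one mixed working standard solution at a series of
#' volumes: the injected mass of each component is its working
#' concentration times the volume, and the area follows the response
#' model plus multiplicative noise. With `noise_model(0, 0)` areas are
#' exactly `slope * mass + intercept`.
#'
#' @param response a [response_model()].
#' @param system a [chrom_system()] (supplies `system_id` and instrument
#'   class).
#' @param volumes_uL injection-volume series (uL); defaults to the
#'   reference series for the system's instrument class.
#' @param concentrations_ug_mL named vector of working-solution
#'   concentrations (ug/mL) by component code.
#' @param retention a [retention_model()].
#' @param noise a [noise_model()].
#' @param seed integer seed; identical seeds give identical tables.
#' @param check_range if `TRUE` (default) warn when an injected mass falls
#'   outside the response model's stated linear range.
#' @return A [peak_table()] with `component_code` and `injected_mass_ug`
#'   filled (these are standards).
#' @export
simulate_standard_series <- function(response = response_model(),
                                     system = uplc_reference_system(),
                                     volumes_uL =
                                       reference_injection_series(system$instrument_class),
                                     concentrations_ug_mL =
                                       reference_working_concentrations(),
                                     retention = retention_model(),
                                     noise = default_noise_model(system$instrument_class),
                                     seed = 1L,
                                     check_range = TRUE) {
  stop_if_not_positive(volumes_uL = volumes_uL,
                       concentrations_ug_mL = concentrations_ug_mL)
  codes <- names(concentrations_ug_mL)
  grid <- expand.grid(component_code = codes, volume = volumes_uL,
                      stringsAsFactors = FALSE)
  grid$mass_ug <- concentrations_ug_mL[grid$component_code] *
    grid$volume / 1000  # ug/mL * uL -> ug (factor 1/1000)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rr <- response_for(response, grid$component_code[i], system$system_id)
    if (check_range && all(c("range_min_ug", "range_max_ug") %in% names(rr)) &&
        (grid$mass_ug[i] < rr$range_min_ug * 0.995 ||
         grid$mass_ug[i] > rr$range_max_ug * 1.005))  # stated ranges are rounded
      warning(sprintf("injected mass %.4g ug of %s outside linear range [%g, %g]",
                      grid$mass_ug[i], grid$component_code[i],
                      rr$range_min_ug, rr$range_max_ug), call. = FALSE)
    data.frame(sample_id = sprintf("std_%g_uL", grid$volume[i]),
               system_id = system$system_id,
               component_code = grid$component_code[i],
               retention_time_min = retention_for(retention,
                                                  grid$component_code[i],
                                                  system$instrument_class),
               mean_area = rr$slope * grid$mass_ug[i] + rr$intercept,
               injection_volume_uL = grid$volume[i],
               injected_mass_ug = grid$mass_ug[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  withr::with_seed(seed, {
    out$area <- noisy_area(out$mean_area, noise)
    out$retention_time_min <- noisy_rt(out$retention_time_min, noise)
  })
  out$mean_area <- NULL
  peak_table(out)
}

#' Simulate sample peak tables for unknowns
#'
#' Converts true contents to injected masses through the extraction
#' parameters (content mg/g x powder g gives mg in the extract; divided
#' by extract volume mL gives ug/uL; times the injection volume gives
#' ug), then applies the response model and noise. Emitted records look
#' like real unknowns: `component_code` and `injected_mass_ug` are blank
#' (assignment and quantification are downstream jobs) unless
#' `label_components = TRUE`.
#'
#' @param profile content profile data frame (`sample_id`,
#'   `component_code`, `content_mg_g`).
#' @param extraction an [extraction_spec()].
#' @param system,response,retention,noise,seed as in
#'   [simulate_standard_series()].
#' @param n_replicates replicate injections per sample; replicate k of
#'   sample S gets `sample_id` `"S.rk"` so table keys stay unique.
#' @param label_components keep the generating `component_code` on each
#'   row (useful for harnesses that bypass peak assignment).
#' @return A [peak_table()].
#' @export
simulate_sample_table <- function(profile = default_content_profile(),
                                  extraction = extraction_spec(),
                                  system = uplc_reference_system(),
                                  response = response_model(),
                                  retention = retention_model(),
                                  noise = default_noise_model(system$instrument_class),
                                  seed = 1L,
                                  n_replicates = 3L,
                                  label_components = FALSE) {
  stopifnot(is.data.frame(profile),
            all(c("sample_id", "component_code", "content_mg_g")
                %in% names(profile)),
            all(profile$content_mg_g >= 0), n_replicates >= 1L)
  v <- system$injection_volume_uL
  rows <- lapply(seq_len(nrow(profile)), function(i) {
    rr <- response_for(response, profile$component_code[i], system$system_id)
    m <- profile$content_mg_g[i] * extraction$sample_mass_g /
      extraction$extract_volume_mL * v  # mg/g*g/mL -> ug/uL; * uL -> ug
    do.call(rbind, lapply(seq_len(n_replicates), function(k) {
      data.frame(sample_id = if (n_replicates == 1L) profile$sample_id[i]
                             else sprintf("%s.r%d", profile$sample_id[i], k),
                 system_id = system$system_id,
                 component_code = profile$component_code[i],
                 retention_time_min = retention_for(retention,
                                                    profile$component_code[i],
                                                    system$instrument_class),
                 mean_area = rr$slope * m + rr$intercept,
                 injection_volume_uL = v,
                 injected_mass_ug = NA_real_, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  withr::with_seed(seed, {
    out$area <- noisy_area(out$mean_area, noise)
    out$retention_time_min <- noisy_rt(out$retention_time_min, noise)
  })
  out$mean_area <- NULL
  if (!label_components) out$component_code <- NA_character_
  peak_table(out)
}

#' Strip replicate suffixes from sample ids
#'
#' [simulate_sample_table()] names replicate injections `"S.r1"`,
#' `"S.r2"`, ...; this recovers the parent sample id.
#'
#' @param sample_id character vector.
#' @return character vector without the `.r<k>` suffix.
#' @export
strip_replicate_suffix <- function(sample_id) {
  sub("\\.r[0-9]+$", "", sample_id)
}
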