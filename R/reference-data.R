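# Published reference measurements for the five-marker longan-leaf assay.
# These constants parameterize the synthetic generator and serve as inputs
# to the reported-value cross-checks; they are transcribed at the precision
# they were printed at (3-5 significant figures), so statistics recomputed
# from them can differ from originally reported ones in the last digit.

#' Reference calibration constants
#'
#' Per-component linear detector response, `area = slope * mass_ug +
#' intercept`, with Pearson r and linear range, for the UPLC and HPLC
#' systems of the longan-leaf assay (six injection volumes of one working
#' solution per system).
#'
#' @return Data frame: `component_code`, `system_id`, `slope`,
#'   `intercept`, `r`, `range_min_ug`, `range_max_ug`.
#' @export
reference_calibrations <- function() {
  data.frame(
    component_code = rep(paste0("C", 1:5), 2),
    system_id = rep(c("UPLC", "HPLC"), each = 5),
    slope = c(7794.28, 9618.87, 19503.76, 16010.58, 17806.81,
              1354.52, 1713.83, 3574.23, 2903.01, 3249.11),
    intercept = c(-16.64, -13.22, -50.67, -7.42, -15.31,
                  17.42, 4.38, 80.52, -3.15, -16.06),
    r = c(0.99988, 0.99972, 0.99992, 0.99983, 0.99976,
          0.99985, 0.99981, 0.99992, 0.99966, 0.99964),
    range_min_ug = c(0.0490, 0.0216, 0.0832, 0.00920, 0.0144,
                     0.490, 0.216, 0.832, 0.0920, 0.144),
    range_max_ug = c(0.245, 0.108, 0.416, 0.0460, 0.0722,
                     2.450, 1.080, 4.160, 0.460, 0.722),
    stringsAsFactors = FALSE)
}

#' Reference multipoint relative correction factors
#'
#' Per-injection-volume relative correction factors f_s/i of the four
#' analytes against quercetin, at six working-solution injection volumes
#' on each system (UPLC 0.2-1.0 uL, HPLC 2-10 uL).
#'
#' @return Long data frame: `system_id`, `injection_volume_uL`,
#'   `component_code`, `f`.
#' @export
reference_multipoint_rcfs <- function() {
  u <- cbind(C1 = c(0.395, 0.397, 0.398, 0.398, 0.398, 0.399),
             C2 = c(0.477, 0.485, 0.487, 0.490, 0.489, 0.490),
             C4 = c(0.805, 0.813, 0.815, 0.816, 0.814, 0.818),
             C5 = c(0.886, 0.900, 0.903, 0.907, 0.906, 0.908))
  h <- cbind(C1 = c(0.379, 0.379, 0.379, 0.379, 0.379, 0.379),
             C2 = c(0.472, 0.476, 0.477, 0.477, 0.478, 0.478),
             C4 = c(0.781, 0.797, 0.800, 0.802, 0.804, 0.806),
             C5 = c(0.894, 0.882, 0.887, 0.891, 0.895, 0.898))
  vol_u <- c(0.2, 0.4, 0.5, 0.6, 0.8, 1.0)
  vol_h <- c(2, 4, 5, 6, 8, 10)
  long <- function(m, sys, vols)
    data.frame(system_id = sys,
               injection_volume_uL = rep(vols, times = ncol(m)),
               component_code = rep(colnames(m), each = nrow(m)),
               f = as.vector(m), stringsAsFactors = FALSE)
  rbind(long(u, "UPLC", vol_u), long(h, "HPLC", vol_h))
}

#' Reference robustness conditions for relative correction factors
#'
#' Multipoint f_s/i values re-measured under nine chromatographic
#' conditions (two UPLC columns, two flow rates, three column
#' temperatures, two HPLC columns).
#'
#' @return Data frame: `condition`, `instrument_class`, and one column
#'   per analyte (`C1`, `C2`, `C4`, `C5`).
#' @export
reference_rcf_robustness <- function() {
  data.frame(
    condition = c("UPLC column Waters", "UPLC column Thermo",
                  "flow 0.2 mL/min", "flow 0.3 mL/min",
                  "temperature 25C", "temperature 30C", "temperature 35C",
                  "HPLC column Phenomenex", "HPLC column Agilent"),
    instrument_class = c(rep("UPLC", 7), rep("HPLC", 2)),
    C1 = c(0.397, 0.398, 0.397, 0.391, 0.393, 0.396, 0.399, 0.376, 0.377),
    C2 = c(0.479, 0.479, 0.481, 0.479, 0.487, 0.481, 0.482, 0.471, 0.471),
    C4 = c(0.817, 0.824, 0.812, 0.803, 0.808, 0.809, 0.818, 0.785, 0.775),
    C5 = c(0.902, 0.901, 0.897, 0.889, 0.925, 0.895, 0.901, 0.879, 0.893),
    stringsAsFactors = FALSE)
}

#' Reference relative retention times
#'
#' Relative retention time of each analyte against quercetin on four
#' column/instrument combinations.
#'
#' @return Data frame: `condition`, `instrument_class`, `C1`, `C2`, `C4`,
#'   `C5`.
#' @export
reference_rrt <- function() {
  data.frame(
    condition = c("UPLC column Waters", "UPLC column Thermo",
                  "HPLC column Phenomenex", "HPLC column Agilent"),
    instrument_class = c("UPLC", "UPLC", "HPLC", "HPLC"),
    C1 = c(0.541, 0.542, 0.495, 0.493),
    C2 = c(0.828, 0.828, 0.844, 0.834),
    C4 = c(1.062, 1.062, 1.086, 1.070),
    C5 = c(1.179, 1.179, 1.180, 1.174),
    stringsAsFactors = FALSE)
}

#' Reference regional contents of the five markers
#'
#' Contents (mg per g of dry leaf powder, mean of 3 injections) of the
#' five markers in longan leaves from ten growing regions of Guangxi,
#' determined by the external-standard method on each instrument.
#'
#' @return Long data frame: `region`, `component_code`, `system_id`,
#'   `content_mg_g`.
#' @export
reference_contents <- function() {
  regions <- c("Beihai", "Qinzhou", "Wuzhou", "Yulin", "Nanning",
               "Chongzuo", "Liuzhou", "Guigang", "Hezhou", "Fangchenggang")
  uplc <- cbind(
    C1 = c(1.918, 2.679, 1.828, 1.631, 2.587, 1.850, 1.259, 1.880, 2.915, 1.462),
    C2 = c(0.356, 0.341, 0.237, 0.261, 0.289, 0.266, 0.303, 0.220, 0.260, 0.286),
    C3 = c(1.073, 2.438, 1.842, 1.799, 1.601, 0.426, 3.521, 2.589, 1.936, 0.699),
    C4 = c(0.144, 0.157, 0.148, 0.140, 0.172, 0.109, 0.145, 0.189, 0.192, 0.129),
    C5 = c(0.225, 0.561, 0.460, 0.425, 0.471, 0.213, 0.892, 0.751, 0.522, 0.358))
  hplc <- cbind(
    C1 = c(1.940, 2.796, 1.824, 1.698, 2.617, 1.827, 1.234, 1.882, 3.002, 1.490),
    C2 = c(0.346, 0.363, 0.225, 0.264, 0.276, 0.243, 0.309, 0.216, 0.262, 0.280),
    C3 = c(0.955, 2.425, 1.835, 1.799, 1.613, 0.443, 3.372, 2.410, 1.918, 0.685),
    C4 = c(0.146, 0.161, 0.150, 0.148, 0.167, 0.115, 0.143, 0.194, 0.184, 0.128),
    C5 = c(0.229, 0.639, 0.469, 0.421, 0.469, 0.210, 0.931, 0.798, 0.571, 0.392))
  long <- function(m, sys)
    data.frame(region = rep(regions, times = ncol(m)),
               component_code = rep(colnames(m), each = nrow(m)),
               system_id = sys, content_mg_g = as.vector(m),
               stringsAsFactors = FALSE)
  rbind(long(uplc, "UPLC"), long(hplc, "HPLC"))
}

#' Reference working-solution concentrations
#'
#' Concentrations (ug/mL) of the mixed working standard solution injected
#' at the calibration volume series.
#'
#' @return Named numeric vector, ug per mL, by component code.
#' @export
reference_working_concentrations <- function() {
  c(C1 = 245.2, C2 = 108.0, C3 = 416.0, C4 = 46.0, C5 = 72.2)
}

#' Reference calibration injection-volume series
#'
#' @param instrument_class `"UPLC"` or `"HPLC"`.
#' @return Numeric vector of injection volumes (uL).
#' @export
reference_injection_series <- function(instrument_class = c("UPLC", "HPLC")) {
  instrument_class <- match.arg(instrument_class)
  if (instrument_class == "UPLC") c(0.2, 0.4, 0.5, 0.6, 0.8, 1.0)
  else c(2, 4, 5, 6, 8, 10)
}
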