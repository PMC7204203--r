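# Geometric method transfer between chromatographic systems: rescale
# flow by column cross-section, injection volume by column volume, and
# gradient times so the gradient delivers the same number of column
# volumes. These are the standard pharmacopoeial scaling rules; porosity
# cancels in every ratio, so column volume is taken proportional to
# d^2 * L.

#' Column geometry and its relative volume
#'
#' @param inner_diameter_mm column inner diameter (mm).
#' @param length_mm column length (mm).
#' @return A `column_geometry` list with a `volume` field proportional to
#'   `d^2 * L` (the proportionality constant cancels in all transfer
#'   ratios).
#' @export
column_geometry <- function(inner_diameter_mm, length_mm) {
  stop_if_not_positive(inner_diameter_mm = inner_diameter_mm,
                       length_mm = length_mm)
  structure(list(inner_diameter_mm = inner_diameter_mm,
                 length_mm = length_mm,
                 volume = inner_diameter_mm^2 * length_mm),
            class = "column_geometry")
}

#' Scale flow rate between columns
#'
#' Preserves linear velocity: `flow_target = flow_original *
#' (d_target / d_original)^2`.
#'
#' @param flow_mL_min original flow rate.
#' @param d_original_mm,d_target_mm inner diameters (mm).
#' @return Target flow rate (mL/min).
#' @export
scale_flow <- function(flow_mL_min, d_original_mm, d_target_mm) {
  stop_if_not_positive(flow_mL_min = flow_mL_min,
                       d_original_mm = d_original_mm,
                       d_target_mm = d_target_mm)
  flow_mL_min * (d_target_mm / d_original_mm)^2
}

#' Scale injection volume between columns
#'
#' Injection volume scales with column volume so the injected band
#' occupies the same fraction of the column:
#' `V_target = V_original * (V_col_target / V_col_original)`.
#'
#' @param injection_uL original injection volume (uL).
#' @param col_original,col_target [column_geometry()] objects (or raw
#'   relative volumes).
#' @return Target injection volume (uL).
#' @export
scale_injection <- function(injection_uL, col_original, col_target) {
  vo <- if (inherits(col_original, "column_geometry")) col_original$volume
        else col_original
  vt <- if (inherits(col_target, "column_geometry")) col_target$volume
        else col_target
  stop_if_not_positive(injection_uL = injection_uL, vo = vo, vt = vt)
  injection_uL * vt / vo
}

#' Scale a gradient program between systems
#'
#' Every breakpoint time is multiplied by
#' `(V_col_target / V_col_original) * (flow_original / flow_target)`, so
#' each gradient segment delivers the same number of column volumes; %A
#' values are untouched.
#'
#' @param gradient gradient data frame (see [chrom_system()]).
#' @param flow_original,flow_target flow rates (mL/min).
#' @param col_original,col_target [column_geometry()] objects.
#' @return Scaled gradient data frame.
#' @export
scale_gradient <- function(gradient, flow_original, flow_target,
                           col_original, col_target) {
  gradient <- validate_gradient(gradient)
  vo <- if (inherits(col_original, "column_geometry")) col_original$volume
        else col_original
  vt <- if (inherits(col_target, "column_geometry")) col_target$volume
        else col_target
  stop_if_not_positive(flow_original = flow_original,
                       flow_target = flow_target, vo = vo, vt = vt)
  fac <- (vt / vo) * (flow_original / flow_target)
  gradient$t_start_min <- gradient$t_start_min * fac
  gradient$t_end_min <- gradient$t_end_min * fac
  gradient
}

#' Transfer a whole system description to a new column
#'
#' Applies [scale_flow()], [scale_injection()] and [scale_gradient()] to
#' derive the conditions on a target column from an existing system —
#' the route by which conventional-bore conditions are derived from a
#' narrow-bore method (or back). Transfers compose (A to B to C equals A
#' to C) and round-trip to the original at machine precision. Real
#' methods are usually fine-tuned afterwards, so transferred times are a
#' starting point, not a claim about any particular instrument.
#'
#' @param system a [chrom_system()].
#' @param target_geometry [column_geometry()] of the target column.
#' @param target_id,target_class,target_column_id labels for the emitted
#'   system.
#' @return A new [chrom_system()].
#' @export
transfer_system <- function(system, target_geometry,
                            target_id = paste0(system$system_id, "_transferred"),
                            target_class = system$instrument_class,
                            target_column_id = "") {
  stopifnot(inherits(system, "chrom_system"),
            inherits(target_geometry, "column_geometry"))
  source_geometry <- column_geometry(system$column_inner_diameter_mm,
                                     system$column_length_mm)
  new_flow <- scale_flow(system$flow_rate_mL_min,
                         system$column_inner_diameter_mm,
                         target_geometry$inner_diameter_mm)
  chrom_system(
    system_id = target_id, instrument_class = target_class,
    column_id = target_column_id,
    column_inner_diameter_mm = target_geometry$inner_diameter_mm,
    column_length_mm = target_geometry$length_mm,
    flow_rate_mL_min = new_flow,
    column_temperature_C = system$column_temperature_C,
    injection_volume_uL = scale_injection(system$injection_volume_uL,
                                          source_geometry, target_geometry),
    gradient = scale_gradient(system$gradient, system$flow_rate_mL_min,
                              new_flow, source_geometry, target_geometry),
    wavelength_program = system$wavelength_program)
}
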