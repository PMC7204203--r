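# Core domain containers: component panels, chromatographic systems and
# peak tables, plus the CSV/YAML interchange every other stage consumes.

PEAK_TABLE_COLS <- c("sample_id", "system_id", "component_code",
                     "retention_time_min", "area", "injection_volume_uL",
                     "injected_mass_ug")
PEAK_TABLE_NUMERIC <- c("retention_time_min", "area", "injection_volume_uL",
                        "injected_mass_ug")

#' Define a panel of components
#'
#' A panel lists the analytes of a QAMS assay and flags the single internal
#' reference: the one component for which a standard is actually run and
#' against which all relative correction factors and relative retention
#' times are expressed.
#'
#' @param code character vector of short unique codes (e.g. `"C1"`).
#' @param name character vector of component names.
#' @param internal_reference single code naming the internal reference.
#' @return A `component_panel`: a data frame with columns `code`, `name`,
#'   `is_internal_reference`.
#' @seealso [longan_panel()] for the five-marker longan-leaf panel.
#' @export
component_panel <- function(code, name, internal_reference) {
  stopifnot(is.character(code), is.character(name),
            length(code) == length(name), length(code) >= 1L,
            is.character(internal_reference), length(internal_reference) == 1L)
  panel <- data.frame(code = code, name = name,
                      is_internal_reference = code == internal_reference,
                      stringsAsFactors = FALSE)
  class(panel) <- c("component_panel", class(panel))
  validate_panel(panel)
  panel
}

#' The five-marker longan-leaf panel
#'
#' Ethyl gallate (C1), astragalin (C2), quercetin (C3), luteolin (C4) and
#' kaempferol (C5), with quercetin as the internal reference. Quercetin is
#' the conventional choice: chemically stable, cheap, and its standard is
#' easy to source.
#'
#' @return A [component_panel()].
#' @export
longan_panel <- function() {
  component_panel(
    code = paste0("C", 1:5),
    name = c("ethyl gallate", "astragalin", "quercetin", "luteolin",
             "kaempferol"),
    internal_reference = "C3")
}

#' Validate a component panel
#'
#' Checks that codes are unique and that exactly one component is flagged
#' as the internal reference.
#'
#' @param panel a [component_panel()] or equivalent data frame.
#' @return The panel, invisibly; errors otherwise.
#' @export
validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel), nrow(panel) >= 1L,
            all(c("code", "is_internal_reference") %in% names(panel)))
  if (anyDuplicated(panel$code))
    stop("duplicate component codes: ",
         paste(unique(panel$code[duplicated(panel$code)]), collapse = ", "),
         call. = FALSE)
  n_ref <- sum(panel$is_internal_reference)
  if (n_ref != 1L)
    stop("a panel must have exactly one internal reference, found ", n_ref,
         call. = FALSE)
  invisible(panel)
}

#' @export
#' @rdname validate_panel
internal_reference_code <- function(panel) {
  validate_panel(panel)
  panel$code[panel$is_internal_reference]
}

# peak tables -------------------------------------------------------------

#' Construct a peak table
#'
#' A peak table holds one row per integrated chromatographic peak:
#' retention time (min), area (arbitrary detector counts), injection
#' volume (uL), and the injected mass (ug) when known (standards) or `NA`
#' (unknowns; `NA` is distinct from a genuine 0 ug blank injection).
#' `component_code` is `NA` until peaks are assigned.
#'
#' @param df data frame with columns `sample_id`, `system_id`,
#'   `component_code`, `retention_time_min`, `area`, `injection_volume_uL`,
#'   `injected_mass_ug` (missing columns are added as `NA` except the
#'   mandatory numeric ones).
#' @return A validated `peak_table` data frame.
#' @export
peak_table <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(sample_id = character(), system_id = character(),
                     component_code = character(),
                     retention_time_min = numeric(), area = numeric(),
                     injection_volume_uL = numeric(),
                     injected_mass_ug = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(df))
  if (!"component_code" %in% names(df)) df$component_code <- NA_character_
  if (!"injected_mass_ug" %in% names(df)) df$injected_mass_ug <- NA_real_
  missing <- setdiff(PEAK_TABLE_COLS, names(df))
  if (length(missing))
    stop("peak table lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[, PEAK_TABLE_COLS, drop = FALSE]
  df$component_code <- as.character(df$component_code)
  validate_peak_table(df)
  class(df) <- unique(c("peak_table", class(df)))
  df
}

validate_peak_table <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!is.finite(df$retention_time_min)) || any(df$retention_time_min <= 0))
    stop("retention_time_min must be positive and finite", call. = FALSE)
  if (any(!is.finite(df$area)) || any(df$area < 0))
    stop("area must be non-negative and finite", call. = FALSE)
  if (any(!is.finite(df$injection_volume_uL)) || any(df$injection_volume_uL <= 0))
    stop("injection_volume_uL must be positive", call. = FALSE)
  key <- paste(df$sample_id, df$system_id, format(df$retention_time_min, digits = 15))
  if (anyDuplicated(key))
    stop("duplicate (sample_id, system_id, retention_time) in peak table",
         call. = FALSE)
  invisible(df)
}

#' Read / write the peak-table CSV dialect
#'
#' The interchange format is comma-separated UTF-8 with a single header
#' row, `.` as decimal separator, and the exact columns `sample_id,
#' system_id, component_code, retention_time_min, area,
#' injection_volume_uL, injected_mass_ug`. Empty cells encode missing
#' values (`NA`): an unknown injected mass is an empty cell, never 0.
#' `write_peak_table()` followed by `read_peak_table()` is the identity on
#' all fields.
#'
#' @param path file path.
#' @return `read_peak_table()` returns a [peak_table()];
#'   `write_peak_table()` returns `path` invisibly.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing <- setdiff(PEAK_TABLE_COLS, names(raw))
  if (length(missing))
    stop("peak-table file ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  raw <- raw[, PEAK_TABLE_COLS, drop = FALSE]
  for (col in PEAK_TABLE_NUMERIC) {
    cell <- trimws(raw[[col]])
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & nzchar(cell) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s' at data line %d of %s",
                   cell[bad[1]], col, bad[1], path), call. = FALSE)
    raw[[col]] <- num
  }
  raw$component_code[!nzchar(trimws(raw$component_code))] <- NA_character_
  peak_table(raw)
}

#' @param table a [peak_table()].
#' @rdname read_peak_table
#' @export
write_peak_table <- function(table, path) {
  table <- peak_table(table)
  out <- as.data.frame(table)
  # full precision so the round-trip is exact
  for (col in PEAK_TABLE_NUMERIC)
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.17g", out[[col]]))
  out$component_code[is.na(out$component_code)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# chromatographic systems -------------------------------------------------

#' Describe a chromatographic system
#'
#' Captures the instrument-side conditions a separation runs under: column
#' geometry, flow rate, temperature, injection volume, gradient program
#' and detection-wavelength program. Used for labelling robustness
#' conditions and as the input to geometric method transfer.
#'
#' @param system_id short label, e.g. `"UPLC"`.
#' @param instrument_class `"UPLC"` or `"HPLC"`.
#' @param column_id free-text column description.
#' @param column_inner_diameter_mm,column_length_mm column geometry (mm).
#' @param flow_rate_mL_min flow rate (mL/min).
#' @param column_temperature_C column temperature (deg C).
#' @param injection_volume_uL injection volume (uL).
#' @param gradient data frame with columns `t_start_min`, `t_end_min`,
#'   `percent_A_start`, `percent_A_end`; times contiguous from 0.
#' @param wavelength_program data frame with columns `from_min`,
#'   `wavelength_nm` (detection wavelength switches).
#' @return A `chrom_system` list.
#' @export
chrom_system <- function(system_id, instrument_class,
                         column_id = "",
                         column_inner_diameter_mm, column_length_mm,
                         flow_rate_mL_min, column_temperature_C = 30,
                         injection_volume_uL,
                         gradient,
                         wavelength_program = NULL) {
  instrument_class <- match.arg(instrument_class, c("UPLC", "HPLC"))
  stop_if_not_positive(column_inner_diameter_mm = column_inner_diameter_mm,
                       column_length_mm = column_length_mm,
                       flow_rate_mL_min = flow_rate_mL_min,
                       injection_volume_uL = injection_volume_uL)
  gradient <- validate_gradient(gradient)
  sys <- list(system_id = system_id, instrument_class = instrument_class,
              column_id = column_id,
              column_inner_diameter_mm = column_inner_diameter_mm,
              column_length_mm = column_length_mm,
              flow_rate_mL_min = flow_rate_mL_min,
              column_temperature_C = column_temperature_C,
              injection_volume_uL = injection_volume_uL,
              gradient = gradient,
              wavelength_program = wavelength_program)
  class(sys) <- "chrom_system"
  sys
}

validate_gradient <- function(gradient) {
  stopifnot(is.data.frame(gradient),
            all(c("t_start_min", "t_end_min", "percent_A_start",
                  "percent_A_end") %in% names(gradient)))
  if (nrow(gradient) == 0L) stop("gradient must have >= 1 step", call. = FALSE)
  with(gradient, {
    if (any(t_end_min <= t_start_min))
      stop("gradient steps need t_end > t_start", call. = FALSE)
    if (gradient$t_start_min[1] != 0)
      stop("gradient must start at t = 0", call. = FALSE)
    if (nrow(gradient) > 1 &&
        any(abs(t_start_min[-1] - t_end_min[-nrow(gradient)]) > 1e-9))
      stop("gradient steps must be contiguous", call. = FALSE)
    pa <- c(percent_A_start, percent_A_end)
    if (any(pa < 0 | pa > 100)) stop("%A must lie in [0, 100]", call. = FALSE)
  })
  gradient
}

#' @export
print.chrom_system <- function(x, ...) {
  cat(sprintf("<chrom_system> %s (%s)\n", x$system_id, x$instrument_class))
  cat(sprintf("  column: %s, %.1f x %.1f mm; %.3g mL/min; %g degC; inj %.3g uL\n",
              x$column_id, x$column_inner_diameter_mm, x$column_length_mm,
              x$flow_rate_mL_min, x$column_temperature_C,
              x$injection_volume_uL))
  g <- x$gradient
  cat("  gradient:",
      paste(sprintf("%g-%g min %g->%g%%A", g$t_start_min, g$t_end_min,
                    g$percent_A_start, g$percent_A_end), collapse = "; "),
      "\n")
  invisible(x)
}

#' Reference UPLC / HPLC systems for the longan-leaf assay
#'
#' The gradient is methanol (A) against 0.2 % phosphoric acid (B):
#' UPLC 0-3 min 20-30 %A, 3-5 min 30-38 %A, 5-20 min 38-75 %A at
#' 0.2 mL/min, 0.5 uL injections; the HPLC analogue runs 0-7, 7-12 and
#' 12-48 min at 1.0 mL/min with 5.0 uL injections. Detection switches
#' from 280 nm to 360 nm after the first-eluting marker. HPLC column
#' geometry defaults to a conventional 4.6 x 150 mm bore, user-overridable
#' since transfer ratios depend only on geometry actually used.
#'
#' @param system_id label recorded in emitted peak tables.
#' @return A [chrom_system()].
#' @export
uplc_reference_system <- function(system_id = "UPLC") {
  chrom_system(system_id, "UPLC", column_id = "HSS C18 2.1x100 mm, 1.8 um",
               column_inner_diameter_mm = 2.1, column_length_mm = 100,
               flow_rate_mL_min = 0.2, column_temperature_C = 30,
               injection_volume_uL = 0.5,
               gradient = data.frame(
                 t_start_min = c(0, 3, 5), t_end_min = c(3, 5, 20),
                 percent_A_start = c(20, 30, 38),
                 percent_A_end = c(30, 38, 75)),
               wavelength_program = data.frame(from_min = c(0, 10),
                                               wavelength_nm = c(280, 360)))
}

#' @rdname uplc_reference_system
#' @export
hplc_reference_system <- function(system_id = "HPLC") {
  chrom_system(system_id, "HPLC", column_id = "C18 4.6x150 mm, 5 um",
               column_inner_diameter_mm = 4.6, column_length_mm = 150,
               flow_rate_mL_min = 1.0, column_temperature_C = 30,
               injection_volume_uL = 5.0,
               gradient = data.frame(
                 t_start_min = c(0, 7, 12), t_end_min = c(7, 12, 48),
                 percent_A_start = c(20, 30, 38),
                 percent_A_end = c(30, 38, 75)),
               wavelength_program = data.frame(from_min = c(0, 22),
                                               wavelength_nm = c(280, 360)))
}

#' Read / write system configuration documents
#'
#' Systems (and optionally the component panel) serialize to a YAML
#' document, one map per system, mirroring the [chrom_system()] fields.
#'
#' @param path file path.
#' @param systems named list of [chrom_system()] objects.
#' @return `read_system_config()` returns a named list of `chrom_system`;
#'   `write_system_config()` returns `path` invisibly.
#' @export
write_system_config <- function(systems, path) {
  if (inherits(systems, "chrom_system")) systems <- list(systems)
  doc <- lapply(systems, function(s) {
    s <- unclass(s)
    s$gradient <- as.list(as.data.frame(s$gradient))
    if (!is.null(s$wavelength_program))
      s$wavelength_program <- as.list(as.data.frame(s$wavelength_program))
    s
  })
  names(doc) <- vapply(systems, `[[`, "", "system_id")
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_system_config
#' @export
read_system_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  out <- lapply(doc, function(s) {
    chrom_system(system_id = s$system_id,
                 instrument_class = s$instrument_class,
                 column_id = s$column_id %||% "",
                 column_inner_diameter_mm = s$column_inner_diameter_mm,
                 column_length_mm = s$column_length_mm,
                 flow_rate_mL_min = s$flow_rate_mL_min,
                 column_temperature_C = s$column_temperature_C %||% 30,
                 injection_volume_uL = s$injection_volume_uL,
                 gradient = as.data.frame(s$gradient),
                 wavelength_program =
                   if (is.null(s$wavelength_program)) NULL
                   else as.data.frame(s$wavelength_program))
  })
  names(out) <- vapply(out, `[[`, "", "system_id")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
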