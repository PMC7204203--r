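# Linear calibration of detector response against injected mass, and its
# inversion for external-standard quantification.

#' Fit a linear calibration curve
#'
#' Ordinary least squares of peak area on injected mass with a free
#' intercept (reference curves all carry intercepts, so regression
#' through the origin is deliberately not used). `r` is the Pearson
#' correlation of mass and area; the linear range is the span of the
#' fitted masses.
#'
#' @param mass_ug injected masses (ug), at least 3 points over at least 2
#'   distinct masses.
#' @param area peak areas.
#' @param component_code,system_id metadata carried on the curve.
#' @return A `calibration_curve`: list with `slope`, `intercept`, `r`,
#'   `range_ug` (length-2), `n_points`, plus the metadata.
#' @export
fit_calibration <- function(mass_ug, area, component_code = NA_character_,
                            system_id = NA_character_) {
  stopifnot(is.numeric(mass_ug), is.numeric(area),
            length(mass_ug) == length(area))
  if (length(mass_ug) < 3L)
    stop("calibration needs >= 3 points", call. = FALSE)
  if (length(unique(mass_ug)) < 2L)
    stop("degenerate design: all calibration masses identical", call. = FALSE)
  fit <- stats::lm(area ~ mass_ug)
  co <- stats::coef(fit)
  calibration_curve(slope = unname(co[2]), intercept = unname(co[1]),
                    r = stats::cor(mass_ug, area),
                    range_ug = range(mass_ug), n_points = length(mass_ug),
                    component_code = component_code, system_id = system_id)
}

#' @param slope,intercept,r,range_ug,n_points curve parameters (see
#'   [fit_calibration()]).
#' @rdname fit_calibration
#' @export
calibration_curve <- function(slope, intercept, r = NA_real_,
                              range_ug = c(NA_real_, NA_real_),
                              n_points = NA_integer_,
                              component_code = NA_character_,
                              system_id = NA_character_) {
  if (!is.na(r) && abs(r) > 1 + 1e-12)
    stop("|r| cannot exceed 1", call. = FALSE)
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  structure(list(component_code = component_code, system_id = system_id,
                 slope = slope, intercept = intercept, r = r,
                 range_ug = range_ug, n_points = n_points),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s / %s: area = %.4f * mass + %.4f (r = %.5f, n = %s)\n",
              x$component_code, x$system_id, x$slope, x$intercept, x$r,
              x$n_points))
  invisible(x)
}

#' Invert a calibration curve (external-standard mass)
#'
#' `mass = (area - intercept) / slope`. Masses outside the curve's linear
#' range (including negative masses when the area falls below the
#' intercept) are returned, not rejected, with the `out_of_range`
#' attribute flagging them; enforcement is the caller's decision.
#'
#' @param curve a `calibration_curve`.
#' @param area peak area(s).
#' @return Numeric masses (ug) with logical attribute `out_of_range`.
#' @export
esm_mass <- function(curve, area) {
  stopifnot(inherits(curve, "calibration_curve"))
  m <- (area - curve$intercept) / curve$slope
  oor <- if (all(is.na(curve$range_ug))) m < 0
         else m < curve$range_ug[1] - 1e-12 | m > curve$range_ug[2] + 1e-12
  attr(m, "out_of_range") <- oor
  m
}

#' Linearity acceptance check
#'
#' @param curve a `calibration_curve`.
#' @param r_threshold minimum acceptable correlation (default 0.9996, the
#'   reference assay's weakest curve).
#' @return `TRUE`/`FALSE`.
#' @export
check_linearity <- function(curve, r_threshold = 0.9996) {
  stopifnot(inherits(curve, "calibration_curve"))
  !is.na(curve$r) && curve$r >= r_threshold
}

#' Fit calibrations for every component in a standard-series peak table
#'
#' @param table a [peak_table()] of standards (`component_code` and
#'   `injected_mass_ug` filled).
#' @return Named list of `calibration_curve` by component code.
#' @export
fit_calibrations <- function(table) {
  stopifnot(inherits(table, "peak_table") || is.data.frame(table))
  std <- table[!is.na(table$component_code) & !is.na(table$injected_mass_ug), ]
  if (!nrow(std)) stop("no standard records (mass + component) in table",
                       call. = FALSE)
  codes <- unique(std$component_code)
  curves <- lapply(codes, function(code) {
    rows <- std[std$component_code == code, ]
    fit_calibration(rows$injected_mass_ug, rows$area, code,
                    rows$system_id[1])
  })
  names(curves) <- codes
  curves
}

#' Serialize / read calibration curves
#'
#' Curves round-trip through the YAML configuration format.
#'
#' @param curves named list of `calibration_curve`.
#' @param path file path.
#' @return `read_calibrations()` returns the named list;
#'   `write_calibrations()` returns `path` invisibly.
#' @export
write_calibrations <- function(curves, path) {
  doc <- lapply(curves, function(cv) {
    cv <- unclass(cv)
    cv$range_ug <- as.numeric(cv$range_ug)
    cv
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_calibrations
#' @export
read_calibrations <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- lapply(doc, function(cv)
    calibration_curve(slope = cv$slope, intercept = cv$intercept, r = cv$r,
                      range_ug = as.numeric(cv$range_ug),
                      n_points = cv$n_points,
                      component_code = cv$component_code,
                      system_id = cv$system_id))
  names(out) <- names(doc)
  out
}
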