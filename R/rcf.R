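# Relative correction factors (RCFs): the heart of single-marker
# multi-component quantification. The multipoint form pairs same-level
# standard injections of analyte and internal reference,
#   f_s/i = (m_s * A_i) / (m_i * A_s),
# while the slope form takes the ratio of calibration slopes,
#   f_s/i = k_i / k_s.
# Since A ~ k * m, the two coincide exactly when intercepts and noise
# vanish; with intercepts the multipoint values drift with level, which
# is what the per-injection-volume dispersion quantifies.

#' Multipoint relative correction factor
#'
#' One same-level pairing of internal-reference standard (mass `m_s`,
#' area `A_s`) against analyte standard (mass `m_i`, area `A_i`):
#' `f = (m_s * A_i) / (m_i * A_s)`.
#'
#' @param m_s,A_s mass (ug) and area of the internal-reference standard.
#' @param m_i,A_i mass (ug) and area of the analyte standard.
#' @return Dimensionless f (vectorized).
#' @export
multipoint_rcf <- function(m_s, A_s, m_i, A_i) {
  stop_if_not_positive(m_s = m_s, A_s = A_s, m_i = m_i, A_i = A_i)
  (m_s * A_i) / (m_i * A_s)
}

#' Aggregate per-level multipoint RCFs
#'
#' @param f vector of per-level f values (>= 2).
#' @return List with `mean` (arithmetic) and `rsd_percent`
#'   (100 * sd / mean, sample sd with n - 1).
#' @export
aggregate_multipoint <- function(f) {
  stop_if_not_positive(f = f)
  if (length(f) < 2L) stop("need >= 2 per-level f values", call. = FALSE)
  list(mean = mean(f), rsd_percent = 100 * stats::sd(f) / mean(f))
}

#' Slope-method relative correction factor
#'
#' @param k_i analyte calibration slope.
#' @param k_s internal-reference calibration slope.
#' @return `k_i / k_s` (vectorized over `k_i`).
#' @export
slope_rcf <- function(k_i, k_s) {
  stop_if_not_positive(k_i = k_i, k_s = k_s)
  k_i / k_s
}

#' Per-level multipoint RCF table from a standard series
#'
#' Pairs each analyte standard with the internal-reference standard of
#' the same injection level (same sample_id, i.e. same working solution
#' and volume) and evaluates [multipoint_rcf()], yielding the
#' per-injection-volume RCF layout with per-analyte mean and RSD.
#'
#' @param table standard-series [peak_table()] with `component_code` and
#'   `injected_mass_ug` filled.
#' @param panel a [component_panel()] identifying the internal reference.
#' @return List: `per_level` (data frame `system_id`,
#'   `injection_volume_uL`, `component_code`, `f`) and `summary` (data
#'   frame `component_code`, `mean`, `rsd_percent`).
#' @export
multipoint_rcf_table <- function(table, panel = longan_panel()) {
  ref_code <- internal_reference_code(panel)
  std <- table[!is.na(table$component_code) & !is.na(table$injected_mass_ug), ]
  ref <- std[std$component_code == ref_code, ]
  ana <- std[std$component_code != ref_code, ]
  if (!nrow(ref)) stop("no internal-reference standards in table", call. = FALSE)
  key <- paste(ref$sample_id, ref$system_id)
  idx <- match(paste(ana$sample_id, ana$system_id), key)
  if (anyNA(idx))
    stop("analyte levels without a matching internal-reference injection",
         call. = FALSE)
  per_level <- data.frame(
    system_id = ana$system_id,
    injection_volume_uL = ana$injection_volume_uL,
    component_code = ana$component_code,
    f = multipoint_rcf(ref$injected_mass_ug[idx], ref$area[idx],
                       ana$injected_mass_ug, ana$area),
    stringsAsFactors = FALSE)
  per_level <- per_level[order(per_level$component_code,
                               per_level$injection_volume_uL), ]
  rownames(per_level) <- NULL
  summary <- do.call(rbind, lapply(split(per_level, per_level$component_code),
    function(d) {
      agg <- aggregate_multipoint(d$f)
      data.frame(component_code = d$component_code[1], mean = agg$mean,
                 rsd_percent = agg$rsd_percent, stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  list(per_level = per_level, summary = summary)
}

#' Slope-method RCFs for a set of calibration curves
#'
#' @param curves named list of `calibration_curve` (see
#'   [fit_calibrations()]).
#' @param panel a [component_panel()].
#' @return Named numeric vector of f values for every non-reference
#'   analyte.
#' @export
slope_rcf_set <- function(curves, panel = longan_panel()) {
  ref_code <- internal_reference_code(panel)
  if (!ref_code %in% names(curves))
    stop("no calibration curve for internal reference ", ref_code,
         call. = FALSE)
  k_s <- curves[[ref_code]]$slope
  ana <- setdiff(names(curves), ref_code)
  vapply(curves[ana], function(cv) slope_rcf(cv$slope, k_s), numeric(1))
}

#' Cross-condition robustness of RCFs
#'
#' RCFs are only useful if stable across instruments, columns, flow rates
#' and temperatures; this summarizes the per-analyte relative standard
#' deviation across a set of condition-labelled RCF determinations.
#'
#' @param conditions data frame with a `condition` column and one numeric
#'   column per analyte (or a list of named f vectors).
#' @return Data frame `component_code`, `mean`, `rsd_percent` across
#'   conditions.
#' @export
robustness_summary <- function(conditions) {
  if (is.list(conditions) && !is.data.frame(conditions)) {
    panels <- lapply(conditions, names)
    if (length(unique(vapply(panels, paste, "", collapse = ","))) != 1L)
      stop("analyte panels differ across conditions", call. = FALSE)
    conditions <- as.data.frame(do.call(rbind, conditions))
  }
  stopifnot(is.data.frame(conditions))
  num <- vapply(conditions, is.numeric, TRUE)
  vals <- conditions[, num, drop = FALSE]
  vals <- vals[, !names(vals) %in% "injection_volume_uL", drop = FALSE]
  if (nrow(vals) < 2L) stop("need >= 2 conditions", call. = FALSE)
  out <- data.frame(component_code = names(vals),
                    mean = vapply(vals, mean, numeric(1)),
                    rsd_percent = vapply(vals, function(x)
                      100 * stats::sd(x) / mean(x), numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
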