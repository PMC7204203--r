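# Quantification of assigned peaks by three routes: ESM (each analyte
# from its own calibration curve), QAMS1 (multipoint-mean RCF against the
# internal reference), and QAMS2 (slope RCF; mass = A_i / (k_s * f),
# which equals A_i / k_i, i.e. ESM with the intercept dropped).

#' External-standard mass for one analyte
#'
#' @param area_i analyte peak area(s).
#' @param curve_i the analyte's own `calibration_curve`.
#' @param component_code if given, checked against the curve's metadata.
#' @return Injected mass (ug), with `out_of_range` attribute from
#'   [esm_mass()].
#' @export
quantify_esm <- function(area_i, curve_i, component_code = NULL) {
  stopifnot(inherits(curve_i, "calibration_curve"))
  if (!is.null(component_code) && !is.na(curve_i$component_code) &&
      component_code != curve_i$component_code)
    stop("curve is for ", curve_i$component_code, ", not ", component_code,
         call. = FALSE)
  esm_mass(curve_i, area_i)
}

#' QAMS mass via a multipoint relative correction factor
#'
#' Rearranges the multipoint RCF definition: with the internal-reference
#' mass `m_s` known (from its own calibration curve) and `f = f_s/i`,
#' `m_i = (m_s * A_i) / (f * A_s)`.
#'
#' @param area_i analyte peak area.
#' @param area_s internal-reference peak area in the same injection.
#' @param mass_s internal-reference mass (ug) in that injection.
#' @param f multipoint-mean relative correction factor f_s/i.
#' @return Injected analyte mass (ug).
#' @export
quantify_qams1 <- function(area_i, area_s, mass_s, f) {
  stop_if_not_positive(area_s = area_s, mass_s = mass_s, f = f)
  stop_if_not_positive(area_i = area_i, .allow_zero = TRUE)
  (mass_s * area_i) / (f * area_s)
}

#' QAMS mass via a slope relative correction factor
#'
#' `m_i = A_i / (k_s * f_s/i)`; since `k_s * f = k_i` this is the
#' analyte's own slope applied without an intercept, which is what makes
#' the ESM - QAMS2 difference a constant `intercept_i / k_i` per
#' injection for each component.
#'
#' @param area_i analyte peak area.
#' @param k_s internal-reference calibration slope.
#' @param f slope relative correction factor f_s/i.
#' @return Injected analyte mass (ug).
#' @export
quantify_qams2 <- function(area_i, k_s, f) {
  stop_if_not_positive(k_s = k_s, f = f)
  stop_if_not_positive(area_i = area_i, .allow_zero = TRUE)
  area_i / (k_s * f)
}

#' Convert an injected mass to a dry-powder content
#'
#' `content [mg/g] = mass_inj [ug] * extract_volume [mL] /
#' (injection_volume [uL] * sample_mass [g])`; the unit factors cancel
#' because ug/uL equals mg/mL. Exact inverse of the forward conversion in
#' [simulate_sample_table()].
#'
#' @param mass_inj_ug injected mass (ug); may be negative (flagged
#'   below-LOD artifact, passed through for transparency).
#' @param injection_volume_uL injection volume (uL).
#' @param extraction an [extraction_spec()].
#' @return Content in mg per g of dry powder.
#' @export
to_content <- function(mass_inj_ug, injection_volume_uL,
                       extraction = extraction_spec()) {
  stop_if_not_positive(injection_volume_uL = injection_volume_uL)
  mass_inj_ug * extraction$extract_volume_mL /
    (injection_volume_uL * extraction$sample_mass_g)
}

#' Quantify an assigned sample table by one or all methods
#'
#' Runs ESM, QAMS1 and/or QAMS2 on every assigned peak, converts masses
#' to contents, and (by default) averages replicate injections — replicate
#' ids of the form `"S.r<k>"` collapse to sample `"S"`.
#'
#' QAMS needs only the internal reference's curve; ESM needs every
#' component's. QAMS1 takes the internal-reference mass from that curve
#' and applies the multipoint-mean f; QAMS2 applies slope f to the
#' reference slope.
#'
#' @param table assigned [peak_table()] (`component_code` filled).
#' @param curves named list of `calibration_curve` (at least the internal
#'   reference's for QAMS methods).
#' @param multipoint_f named numeric of multipoint-mean f per analyte
#'   (required for QAMS1).
#' @param slope_f named numeric of slope f per analyte (required for
#'   QAMS2).
#' @param panel a [component_panel()].
#' @param extraction an [extraction_spec()].
#' @param methods subset of `c("ESM", "QAMS1", "QAMS2")`.
#' @param average_replicates collapse `.r<k>` replicate suffixes and
#'   average contents.
#' @return Data frame `sample_id`, `component_code`, `method`,
#'   `injected_mass_ug`, `content_mg_g`, `flag` (`"out_of_range"` when
#'   any contributing ESM inversion left the linear range, else `""`).
#' @export
quantify_samples <- function(table, curves,
                             multipoint_f = NULL, slope_f = NULL,
                             panel = longan_panel(),
                             extraction = extraction_spec(),
                             methods = c("ESM", "QAMS1", "QAMS2"),
                             average_replicates = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  ref_code <- internal_reference_code(panel)
  tab <- table[!is.na(table$component_code), , drop = FALSE]
  if (!nrow(tab)) stop("no assigned peaks to quantify", call. = FALSE)
  if ("QAMS1" %in% methods && is.null(multipoint_f))
    stop("QAMS1 requires multipoint_f", call. = FALSE)
  if ("QAMS2" %in% methods && is.null(slope_f))
    stop("QAMS2 requires slope_f", call. = FALSE)
  if (any(c("QAMS1", "QAMS2") %in% methods) && !ref_code %in% names(curves))
    stop("QAMS needs the internal reference curve (", ref_code, ")",
         call. = FALSE)

  key <- paste(tab$sample_id, tab$system_id)
  ref_rows <- tab[tab$component_code == ref_code, ]
  ref_idx <- match(key, paste(ref_rows$sample_id, ref_rows$system_id))

  out <- list()
  for (i in seq_len(nrow(tab))) {
    code <- tab$component_code[i]
    area <- tab$area[i]
    for (method in methods) {
      flag <- ""
      mass <- switch(method,
        ESM = {
          if (!code %in% names(curves))
            stop("ESM needs a calibration curve for ", code, call. = FALSE)
          m <- quantify_esm(area, curves[[code]], code)
          if (attr(m, "out_of_range")) flag <- "out_of_range"
          as.numeric(m)
        },
        QAMS1 = {
          if (is.na(ref_idx[i]))
            stop("no internal-reference peak for sample ", tab$sample_id[i],
                 call. = FALSE)
          if (code == ref_code) {
            as.numeric(esm_mass(curves[[ref_code]], area))
          } else {
            if (!code %in% names(multipoint_f))
              stop("no multipoint f for ", code, call. = FALSE)
            m_s <- esm_mass(curves[[ref_code]], ref_rows$area[ref_idx[i]])
            if (attr(m_s, "out_of_range")) flag <- "out_of_range"
            quantify_qams1(area, ref_rows$area[ref_idx[i]], as.numeric(m_s),
                           multipoint_f[[code]])
          }
        },
        QAMS2 = {
          if (code == ref_code) {
            quantify_qams2(area, curves[[ref_code]]$slope, 1)
          } else {
            if (!code %in% names(slope_f))
              stop("no slope f for ", code, call. = FALSE)
            quantify_qams2(area, curves[[ref_code]]$slope, slope_f[[code]])
          }
        })
      out[[length(out) + 1L]] <- data.frame(
        sample_id = tab$sample_id[i], component_code = code, method = method,
        injected_mass_ug = mass,
        content_mg_g = to_content(mass, tab$injection_volume_uL[i],
                                  extraction),
        flag = flag, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (average_replicates) {
    res$sample_id <- strip_replicate_suffix(res$sample_id)
    agg <- stats::aggregate(
      cbind(injected_mass_ug, content_mg_g) ~
        sample_id + component_code + method,
      data = res, FUN = mean)
    flags <- stats::aggregate(
      flag ~ sample_id + component_code + method, data = res,
      FUN = function(fl) if (any(nzchar(fl))) "out_of_range" else "")
    res <- merge(agg, flags,
                 by = c("sample_id", "component_code", "method"))
  }
  res <- res[order(res$method, res$component_code, res$sample_id), ]
  rownames(res) <- NULL
  res
}
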