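# Rendering peak tables into sampled chromatograms and integrating them
# back, so the peak-table ingestion boundary can be exercised end-to-end
# (render -> integrate -> quantify round-trips).

#' Render a peak table as a sampled chromatogram
#'
#' Each peak becomes a Gaussian centred at its retention time whose
#' integral (in intensity x minutes) equals the record's area, on top of
#' an optionally drifting baseline with additive noise. Signals are
#' sampled uniformly at `sampling_rate_hz`.
#'
#' @param table a [peak_table()] (one sample/system; peaks of several
#'   samples would overlap meaninglessly).
#' @param peak_width_sd_min Gaussian sd of each peak, minutes.
#' @param sampling_rate_hz samples per second; must give at least 10
#'   samples per peak sd.
#' @param baseline_level constant baseline intensity.
#' @param baseline_drift_per_min linear drift, intensity per minute.
#' @param noise_sd additive Gaussian noise sd on the sampled intensity.
#' @param run_time_min total run time; default extends 5 sd past the last
#'   peak.
#' @param seed integer seed for the additive noise.
#' @return Data frame `time_min`, `intensity`.
#' @export
render_chromatogram <- function(table, peak_width_sd_min = 0.05,
                                sampling_rate_hz = 5,
                                baseline_level = 0,
                                baseline_drift_per_min = 0,
                                noise_sd = 0, run_time_min = NULL,
                                seed = 1L) {
  stop_if_not_positive(peak_width_sd_min = peak_width_sd_min,
                       sampling_rate_hz = sampling_rate_hz)
  dt_min <- 1 / (sampling_rate_hz * 60)
  if (dt_min > peak_width_sd_min / 10)
    stop(sprintf(paste0("sampling rate too low: %.3g Hz gives %.3g samples ",
                        "per peak sd; need >= 10"),
                 sampling_rate_hz, peak_width_sd_min / dt_min), call. = FALSE)
  if (is.null(run_time_min))
    run_time_min <- if (nrow(table)) max(table$retention_time_min) +
      5 * peak_width_sd_min else 1
  if (nrow(table) && max(table$retention_time_min) +
        3 * peak_width_sd_min > run_time_min)
    stop("peaks fall outside the run time", call. = FALSE)
  t <- seq(0, run_time_min, by = dt_min)
  y <- baseline_level + baseline_drift_per_min * t
  for (i in seq_len(nrow(table)))
    y <- y + table$area[i] *
      stats::dnorm(t, table$retention_time_min[i], peak_width_sd_min)
  if (noise_sd > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(length(t), sd = noise_sd))
  data.frame(time_min = t, intensity = y)
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

#' Integrate a sampled chromatogram into a peak table
#'
#' Detects local maxima whose prominence above the flanking valleys
#' exceeds `min_prominence`, sets peak boundaries at those valleys (or
#' the signal edges), and computes each area by the trapezoidal rule
#' after subtracting the straight line joining the boundary points. The
#' apex time becomes the retention time.
#'
#' @param signal data frame `time_min`, `intensity`, uniformly sampled.
#' @param min_prominence minimum apex height above the higher flanking
#'   valley for a maximum to count as a peak.
#' @param sample_id,system_id,injection_volume_uL metadata stamped onto
#'   the emitted records.
#' @return A [peak_table()]; empty (no error) when nothing exceeds the
#'   prominence threshold.
#' @export
integrate_chromatogram <- function(signal, min_prominence = 1,
                                   sample_id = "sample",
                                   system_id = "sim",
                                   injection_volume_uL = 1) {
  stopifnot(is.data.frame(signal),
            all(c("time_min", "intensity") %in% names(signal)))
  t <- signal$time_min; y <- signal$intensity
  n <- length(y)
  dt <- diff(t)
  if (n >= 3 && (max(dt) - min(dt)) > 1e-6 * stats::median(dt))
    stop("signal must be uniformly sampled", call. = FALSE)
  empty <- peak_table()
  if (n < 3) return(empty)
  apex <- which(y[-c(1, n)] > y[-c(n - 1, n)] &
                y[-c(1, n)] >= y[-c(1, 2)]) + 1L
  if (!length(apex)) return(empty)
  # valleys: local minima plus the two edges
  valley <- c(1L, which(y[-c(1, n)] <= y[-c(n - 1, n)] &
                        y[-c(1, n)] <= y[-c(1, 2)]) + 1L, n)
  rows <- lapply(apex, function(a) {
    lo <- max(valley[valley < a])
    hi <- min(valley[valley > a])
    prom <- y[a] - max(y[lo], y[hi])
    if (prom < min_prominence) return(NULL)
    idx <- lo:hi
    base <- y[lo] + (y[hi] - y[lo]) * (t[idx] - t[lo]) / (t[hi] - t[lo])
    data.frame(sample_id = sample_id, system_id = system_id,
               component_code = NA_character_,
               retention_time_min = t[a],
               area = max(0, trapezoid(t[idx], y[idx] - base)),
               injection_volume_uL = injection_volume_uL,
               injected_mass_ug = NA_real_, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  peak_table(do.call(rbind, rows))
}
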