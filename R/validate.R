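# Method-validation statistics: relative standard deviation (the assay's
# dispersion metric throughout), spike recovery, and Pearson agreement
# between instruments or quantification methods.

#' Relative standard deviation
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation, the
#' standard analytical-chemistry convention.
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return RSD in percent.
#' @export
rsd <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("rsd needs >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("rsd undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Spike recovery
#'
#' `100 * (found_total - original) / added`: the percentage of a known
#' spiked amount re-measured after extraction.
#'
#' @param found_total total amount measured in the spiked portion.
#' @param original amount present before spiking (same units).
#' @param added spiked amount (> 0, same units).
#' @return Recovery in percent (vectorized).
#' @export
recovery_percent <- function(found_total, original, added) {
  stop_if_not_positive(added = added)
  100 * (found_total - original) / added
}

#' Pearson correlation with two-tailed significance
#'
#' Product-moment r with the p-value from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom,
#' two-tailed (via [stats::cor.test()]).
#'
#' @param x,y equal-length numeric vectors (n >= 3, both with nonzero
#'   variance).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("pearson_r needs n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-component agreement between two instruments or methods
#'
#' Pairs quantification results by (sample, component) across two labels
#' of a pairing column (`system/instrument` or `method`) and reports the
#' per-component Pearson r, two-tailed p and significance at alpha.
#'
#' @param quant data frame with columns `sample_id`, `component_code`,
#'   a pairing column, and `content_mg_g`.
#' @param pair_by name of the pairing column (e.g. `"method"` or
#'   `"system_id"`).
#' @param levels the two labels to pair, e.g. `c("ESM", "QAMS1")`.
#' @param alpha significance level (default 0.01, two-tailed).
#' @return Data frame `component_code`, `n`, `r`, `p`, `significant`.
#' @export
agreement_report <- function(quant, pair_by, levels, alpha = 0.01) {
  stopifnot(is.data.frame(quant), pair_by %in% names(quant),
            length(levels) == 2L,
            all(c("sample_id", "component_code", "content_mg_g")
                %in% names(quant)))
  a <- quant[quant[[pair_by]] == levels[1], ]
  b <- quant[quant[[pair_by]] == levels[2], ]
  key_a <- paste(a$sample_id, a$component_code)
  key_b <- paste(b$sample_id, b$component_code)
  missing <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
  if (length(missing))
    stop("unpaired (sample, component) keys: ",
         paste(utils::head(missing, 5), collapse = "; "), call. = FALSE)
  b <- b[match(key_a, key_b), ]
  out <- do.call(rbind, lapply(split(seq_len(nrow(a)), a$component_code),
    function(idx) {
      pr <- pearson_r(a$content_mg_g[idx], b$content_mg_g[idx])
      data.frame(component_code = a$component_code[idx[1]], n = pr$n,
                 r = pr$r, p = pr$p, significant = pr$p < alpha,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Simulate a spike-recovery experiment
#'
#' Emulates the accuracy check of the reference assay: `n_portions`
#' portions of powder with known contents are each spiked with a known
#' standard amount (default equal to the native amount), extracted, run
#' on the given system with measurement noise, and quantified by ESM;
#' recovery is `(found_total - original) / added`.
#'
#' @param profile single-sample content profile (`component_code`,
#'   `content_mg_g`); defaults to the first region of
#'   [default_content_profile()].
#' @param portion_mass_g powder mass per spiked portion (default 2.0 g).
#' @param spike_ratio spiked amount as a fraction of the native amount.
#' @param n_portions number of spiked portions (default 9).
#' @param system,response,retention,noise,extraction,seed generator
#'   settings; extraction volume defaults to the assay's 20 mL.
#' @return Data frame `portion`, `component_code`, `original_mg`,
#'   `added_mg`, `found_mg`, `recovery_percent`.
#' @export
simulate_spike_recovery <- function(profile = NULL,
                                    portion_mass_g = 2.0,
                                    spike_ratio = 1.0,
                                    n_portions = 9L,
                                    system = uplc_reference_system(),
                                    response = response_model(),
                                    retention = retention_model(),
                                    noise = default_noise_model(system$instrument_class),
                                    extraction = extraction_spec(
                                      sample_mass_g = portion_mass_g),
                                    seed = 1L) {
  if (is.null(profile)) {
    prof <- default_content_profile()
    profile <- prof[prof$sample_id == prof$sample_id[1],
                    c("component_code", "content_mg_g")]
  }
  stop_if_not_positive(portion_mass_g = portion_mass_g,
                       spike_ratio = spike_ratio)
  # standards series for the curves (noiseless fit is not the point of a
  # recovery check; fit on the same noise level as the measurements)
  std <- simulate_standard_series(response = response, system = system,
                                  retention = retention, noise = noise,
                                  seed = seed + 1L)
  curves <- fit_calibrations(std)
  spiked <- do.call(rbind, lapply(seq_len(n_portions), function(p)
    data.frame(sample_id = sprintf("portion%02d", p),
               component_code = profile$component_code,
               content_mg_g = profile$content_mg_g * (1 + spike_ratio),
               stringsAsFactors = FALSE)))
  tab <- simulate_sample_table(spiked, extraction = extraction,
                               system = system, response = response,
                               retention = retention, noise = noise,
                               seed = seed, n_replicates = 1L,
                               label_components = TRUE)
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    code <- tab$component_code[i]
    mass <- as.numeric(quantify_esm(tab$area[i], curves[[code]], code))
    found_mg <- mass / tab$injection_volume_uL[i] *
      extraction$extract_volume_mL  # ug/uL == mg/mL, times mL -> mg
    original_mg <- profile$content_mg_g[profile$component_code == code] *
      portion_mass_g
    added_mg <- original_mg * spike_ratio
    data.frame(portion = strip_replicate_suffix(tab$sample_id[i]),
               component_code = code, original_mg = original_mg,
               added_mg = added_mg, found_mg = found_mg,
               recovery_percent = recovery_percent(found_mg, original_mg,
                                                   added_mg),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
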