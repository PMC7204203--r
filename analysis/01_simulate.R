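#!/usr/bin/env Rscript
# Stage 1 — generate the study's raw material: working-solution standard
# series and 10-region sample peak tables on both instruments, at the
# instruments' noise scales, plus one rendered chromatogram trace.
# Everything downstream runs from the files written here.

suppressPackageStartupMessages(library(qamskit))
seed <- as.integer(Sys.getenv("QAMS_SEED", "1"))
dir.create("results", showWarnings = FALSE)

systems <- list(UPLC = uplc_reference_system(), HPLC = hplc_reference_system())
write_system_config(systems, "results/systems.yaml")

for (sys in systems) {
  noise <- default_noise_model(sys$instrument_class)
  std <- simulate_standard_series(system = sys, noise = noise, seed = seed)
  write_peak_table(std, sprintf("results/standards_%s.csv", sys$system_id))

  samples <- simulate_sample_table(system = sys, noise = noise,
                                   seed = seed + 10L, n_replicates = 3L)
  write_peak_table(samples, sprintf("results/samples_%s.csv", sys$system_id))
  message(sprintf("%s: %d standard and %d sample records (area RSD %.1f%%)",
                  sys$system_id, nrow(std), nrow(samples), noise$area_rsd))
}

# a Fig.-3-like trace of one UPLC sample injection, for eyeballing
one <- read_peak_table("results/samples_UPLC.csv")
one <- peak_table(one[one$sample_id == "Beihai.r1", ])
sig <- render_chromatogram(one, peak_width_sd_min = 0.05,
                           sampling_rate_hz = 5, baseline_level = 5,
                           noise_sd = 0.5, seed = seed)
utils::write.csv(sig, "results/chromatogram_Beihai_UPLC.csv",
                 row.names = FALSE)
message("wrote results/standards_*.csv, samples_*.csv, systems.yaml, ",
        "chromatogram_Beihai_UPLC.csv (seed ", seed, ")")
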