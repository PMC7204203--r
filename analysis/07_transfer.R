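#!/usr/bin/env Rscript
# Stage 7 — geometric method transfer: derive conventional-bore (HPLC)
# conditions from the narrow-bore UPLC method and verify the transfer
# round-trips. Transferred times are a starting point; bench methods are
# normally fine-tuned afterwards.

suppressPackageStartupMessages(library(qamskit))

uplc <- read_system_config("results/systems.yaml")$UPLC
target <- column_geometry(4.6, 150)
hplc_derived <- transfer_system(uplc, target, target_id = "HPLC_derived",
                                target_class = "HPLC",
                                target_column_id = "C18 4.6x150 mm")
write_system_config(list(uplc, hplc_derived), "results/systems_transferred.yaml")
print(hplc_derived)

back <- transfer_system(hplc_derived,
                        column_geometry(uplc$column_inner_diameter_mm,
                                        uplc$column_length_mm),
                        target_id = "UPLC_back", target_class = "UPLC")
stopifnot(abs(back$flow_rate_mL_min - uplc$flow_rate_mL_min) < 1e-9,
          abs(back$injection_volume_uL - uplc$injection_volume_uL) < 1e-9,
          max(abs(back$gradient$t_end_min - uplc$gradient$t_end_min)) < 1e-9)
message("transfer round-trip UPLC -> 4.6x150 mm -> UPLC is exact")
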