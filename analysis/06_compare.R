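#!/usr/bin/env Rscript
# Stage 6 — the agreement analysis: per-component Pearson correlation of
# ESM contents across instruments, and of QAMS1/QAMS2 against ESM within
# each instrument, with two-tailed significance at alpha = 0.01; plus a
# per-component scatter figure when ggplot2 is available.

suppressPackageStartupMessages(library(qamskit))

quant <- utils::read.csv("results/quantification.csv")

esm <- quant[quant$method == "ESM", ]
inst <- agreement_report(esm, pair_by = "system_id",
                         levels = c("UPLC", "HPLC"))
inst$comparison <- "UPLC vs HPLC (ESM)"

meth <- list()
for (sys_id in c("UPLC", "HPLC")) {
  qs <- quant[quant$system_id == sys_id, ]
  for (other in c("QAMS1", "QAMS2")) {
    a <- agreement_report(qs, pair_by = "method", levels = c("ESM", other))
    a$comparison <- sprintf("ESM vs %s (%s)", other, sys_id)
    meth[[length(meth) + 1L]] <- a
  }
}
report <- rbind(inst, do.call(rbind, meth))
report$r <- round_half_up(report$r, 3)
utils::write.csv(report, "results/agreement_report.csv", row.names = FALSE)
print(report)
message(sprintf("minimum Pearson r across all comparisons: %.3f", min(report$r)))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  wide <- merge(esm[esm$system_id == "UPLC",
                    c("sample_id", "component_code", "content_mg_g")],
                esm[esm$system_id == "HPLC",
                    c("sample_id", "component_code", "content_mg_g")],
                by = c("sample_id", "component_code"),
                suffixes = c("_UPLC", "_HPLC"))
  p <- ggplot(wide, aes(content_mg_g_UPLC, content_mg_g_HPLC)) +
    geom_abline(linetype = 2, colour = "grey60") +
    geom_point(size = 1.5) +
    facet_wrap(~component_code, scales = "free") +
    labs(x = "UPLC content (mg/g)", y = "HPLC content (mg/g)",
         title = "Cross-instrument agreement of ESM contents") +
    theme_bw()
  ggsave("results/agreement_scatter.pdf", p, width = 8, height = 5)
  message("wrote results/agreement_scatter.pdf")
}
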