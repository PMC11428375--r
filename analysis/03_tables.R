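#!/usr/bin/env Rscript
# Reduce the sweep metrics to the two headline tables: per tissue the top-3
# sources by penetration depth at the 1%/0.1%/0.01% energy levels, and per
# tissue/axis the top-3 and bottom-3 sources by FWHM at 12 mm depth.
#
# Run after analysis/02_sweep.R:  Rscript analysis/03_tables.R

library(voxmc)

metrics <- read.csv("results/02_sweep_metrics.csv")
tabs <- make_tables(metrics, k = 3)

write.csv(tabs$depth, "results/03_depth_table.csv", row.names = FALSE)
write.csv(tabs$fwhm, "results/03_fwhm_table.csv", row.names = FALSE)

message("top-3 penetration depth sources per tissue (1% level):")
d1 <- tabs$depth[tabs$depth$level == 1, ]
for (ti in unique(d1$tissue)) {
  rows <- d1[d1$tissue == ti, ]
  message(sprintf("  %-20s %s", ti,
                  paste(sprintf("%s (%.1f mm)", rows$source, rows$depth_mm),
                        collapse = ", ")))
}
message("FWHM extremes at 12 mm (x axis):")
fx <- tabs$fwhm[tabs$fwhm$axis == "x" & tabs$fwhm$rank == 1, ]
for (i in seq_len(nrow(fx))) {
  message(sprintf("  %-20s %s: %s (%.1f mm)", fx$tissue[i], fx$extreme[i],
                  fx$source[i], fx$width_mm[i]))
}
message("note: FWHM at 12 mm needs ~1e8 photons/cell to be smooth; at the")
message("reduced sweep counts these widths are noise-dominated (see the")
message("methods vignette), while the depth rankings are already stable.")
message("wrote results/03_depth_table.csv, results/03_fwhm_table.csv")
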