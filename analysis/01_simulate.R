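#!/usr/bin/env Rscript
# Stage 1 — simulate the cooked chicken-breast study.
#
# Generates the 72-sample synthetic study (36 breasts, two slices each,
# cooked at 50/60/70 deg C) with hyperspectral scans on a 400-1000 nm grid,
# writes the oven-drying reference table, and exports one example scan in
# ENVI format (raw counts + white/dark references + ground-truth moisture
# map) so downstream stages can be demonstrated from files on disk.

suppressMessages(library(hsimoist))

out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- synth_config(seed = 1L)
dataset <- generate_dataset(config)

write.csv(dataset$reference, file.path(out, "reference_table.csv"),
          row.names = FALSE)

s1 <- dataset$cubes[[1]]
write_envi(s1$raw, file.path(out, "example_raw.hdr"), dtype = 5L)
write_envi(hypercube(dataset$refs$white, dataset$wavelengths, "raw"),
           file.path(out, "example_white.hdr"), dtype = 5L)
write_envi(hypercube(dataset$refs$dark, dataset$wavelengths, "raw"),
           file.path(out, "example_dark.hdr"), dtype = 5L)
tm <- s1$truth$pixel_map; tm[is.na(tm)] <- -9999
write_envi(hypercube(array(tm, c(dim(tm), 1)), 0, "raw"),
           file.path(out, "example_truth_map.hdr"), dtype = 5L)

ref <- dataset$reference
cat(sprintf("simulated %d samples (%d breasts x %d slices)\n",
            nrow(ref), config$n_breasts, config$slices_per_breast))
for (tp in c(50, 60, 70)) {
  m <- ref$moisture_pct[ref$temperature_C == tp]
  cat(sprintf("  %d degC: n = %2d, moisture %.1f-%.1f%% (mean %.1f%%)\n",
              tp, length(m), min(m), max(m), mean(m)))
}
cat(sprintf("reference table -> %s\n", file.path(out, "reference_table.csv")))
cat("example ENVI scan (raw + white/dark + truth map) -> results/example_*.hdr\n")
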