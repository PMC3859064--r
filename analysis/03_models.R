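#!/usr/bin/env Rscript
# Stage 3 — preprocessing comparison and PLS regression.
#
# Reads the mean spectra and the oven-drying reference table produced by
# stages 1-2, splits 52 calibration / 20 test samples, and for each of the
# eight pre-treatments runs leave-one-out cross-validation (component count
# at the lowest RMSE) and reports calibration / validation / prediction
# statistics — once over the full 400-1000 nm range and once over the
# 700-1000 nm NIR subset.

suppressMessages(library(hsimoist))

out <- "results"
spectra <- read.csv(file.path(out, "mean_spectra.csv"))
reference <- load_reference_table(file.path(out, "reference_table.csv"))
stopifnot(identical(spectra$sample_id, reference$sample_id))
X <- as.matrix(spectra[, -1])
wl <- as.numeric(sub("^nm", "", names(spectra)[-1]))
y <- reference$moisture_pct

reports <- list()
ranges <- list(full = c(400, 1000), nir = c(700, 1000))
for (nm in names(ranges)) {
  keep <- wl >= ranges[[nm]][1] & wl <= ranges[[nm]][2]
  sel <- select_model(X[, keep], y, wl[keep], max_lv = 20, n_train = 52,
                      seed = 1)
  cat(sprintf("== %s range (%d-%d nm, %d bands): best by SEV = %s\n",
              nm, ranges[[nm]][1], ranges[[nm]][2], sum(keep),
              sel$best_method))
  print(transform(sel$report, r2_c = round(r2_c, 3), sec = round(sec, 3),
                  r2_v = round(r2_v, 3), sev = round(sev, 3),
                  r2_p = round(r2_p, 3), sep = round(sep, 3)),
        row.names = FALSE)
  reports[[nm]] <- cbind(range = nm, sel$report)
}
report <- do.call(rbind, reports)
write.csv(report, file.path(out, "report.csv"), row.names = FALSE)
cat(sprintf("report table -> %s\n", file.path(out, "report.csv")))
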