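#!/usr/bin/env Rscript
# Step 2: preprocess the raw cohort.
#
# Savitzky-Golay smoothing (9-point window, degree-5 polynomial), airPLS
# baseline removal (lambda = 1e4) to strip the serum autofluorescence,
# then vector normalization so every spectrum has unit Euclidean norm.

library(sersdx)

raw <- read_spectrumset("results/cohort_raw.csv")
proc <- preprocess_pipeline(raw, preprocess_config())
write_spectrumset(proc, "results/spectra_processed.csv")

for (st in attr(proc, "trace")) {
  cat("stage:", st$stage, "\n")
}
cat(sprintf("row norms after normalization: %.6f-%.6f\n",
            min(sqrt(rowSums(proc$intensities^2))),
            max(sqrt(rowSums(proc$intensities^2)))))
cat("wrote results/spectra_processed.csv\n")
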