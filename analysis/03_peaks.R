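#!/usr/bin/env Rscript
# Step 3: peak-level group comparison.
#
# Mean and difference spectra for each pair of groups, then per-peak
# one-way ANOVA across the three groups at the 11 characteristic serum
# wavenumbers (alpha = 0.05, no multiplicity correction; a Bonferroni
# column is included for reference).

library(sersdx)

proc <- read_spectrumset("results/spectra_processed.csv")

pairs <- list(c("stone", "polyp"), c("stone", "healthy"),
              c("polyp", "healthy"))
for (pr in pairs) {
  d <- mean_and_difference_spectra(proc, pr[1], pr[2])
  out <- sprintf("results/difference_%s_vs_%s.csv", pr[1], pr[2])
  write.csv(d, out, row.names = FALSE)
  cat(sprintf("%s - %s: |difference| peaks at %d cm^-1\n", pr[1], pr[2],
              d$wavenumber[which.max(abs(d$difference))]))
}

tab <- anova_peaks(proc)
write.csv(tab, "results/peak_anova.csv", row.names = FALSE)
cat("\nsignificant peaks (p < 0.05):",
    paste(tab$wavenumber[tab$significant], collapse = ", "), "cm^-1\n")
cat("non-significant:",
    paste(tab$wavenumber[!tab$significant], collapse = ", "), "cm^-1\n")
cat("wrote results/peak_anova.csv and difference spectra tables\n")
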