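#!/usr/bin/env Rscript
# Step 4: triple and binary classification with OPLS-DA and PCA-LDA.
#
# Both classifiers are assessed with stratified 10-fold cross-validation
# (pooled out-of-fold confusion matrices, the diagnostic-table
# sensitivity/specificity conventions, one-vs-rest AUC). The OPLS-DA
# score table for the 2-D score plot is exported with its 95% Hotelling
# T2 ellipse parameters.

library(sersdx)

seed <- 20230601
proc <- read_spectrumset("results/spectra_processed.csv")

report_cv <- function(set, label, folds = 10) {
  specs <- list(opls = list(model = "opls", n_orthogonal = 1),
                pcalda = list(model = "pcalda"))
  for (m in names(specs)) {
    cv <- kfold_cv(set, model_spec = specs[[m]], folds = folds, seed = seed)
    cat(sprintf("\n== %s, %s (10-fold CV) ==\n", label, m))
    print(cv$report)
    write.csv(as.data.frame(cv$report$confusion),
              sprintf("results/cv_confusion_%s_%s.csv", label, m),
              row.names = FALSE)
  }
}

report_cv(proc, "triple")

# binary problems: each disease pair plus case (stone+polyp) vs healthy
pairs <- list(stone_vs_polyp = c("stone", "polyp"),
              stone_vs_healthy = c("stone", "healthy"),
              polyp_vs_healthy = c("polyp", "healthy"))
for (nm in names(pairs)) {
  sub <- subset_samples(proc, proc$labels %in% pairs[[nm]])
  report_cv(sub, nm)
}
case <- spectrum_set(proc$wavenumbers, proc$intensities,
                     ifelse(proc$labels == "healthy", "healthy", "case"),
                     proc$sample_ids)
report_cv(case, "case_vs_healthy")

# score table for the triple OPLS-DA model
fit <- fit_opls(proc, n_orthogonal = 1, cv_folds = 10, seed = seed)
print(fit)
sp <- scores_for_plot(fit)
write.csv(sp$scores, "results/opls_scores_triple.csv", row.names = FALSE)
cat(sprintf("95%% ellipse semi-axes: %.3f x %.3f\n",
            sp$ellipse$semi_axes[1], sp$ellipse$semi_axes[2]))
cat("wrote CV confusion tables and results/opls_scores_triple.csv\n")
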