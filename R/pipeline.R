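#' Assemble a pipeline run configuration
#'
#' Collects everything one end-to-end run needs: the input (a CSV path or
#' a [cohort_config()] to simulate), preprocessing parameters, the model
#' choice and settings, validation settings and the master seed. A seed is
#' mandatory because the stratified CV split and the permutation test are
#' stochastic.
#'
#' @param input path to a wide SpectrumSet CSV, or `NULL` to simulate.
#' @param cohort a [cohort_config()] used when `input` is `NULL`.
#' @param preprocess a [preprocess_config()].
#' @param model `"opls"`, `"pcalda"` or `"both"`.
#' @param opls list of OPLS settings (`n_predictive`, `n_orthogonal`).
#' @param pcalda list of PCA-LDA settings (`var_explained`,
#'   `n_components`).
#' @param folds cross-validation folds.
#' @param n_perm permutations for the validity test (0 disables it).
#' @param seed master integer seed.
#' @param outdir optional output directory; when given, all tables and a
#'   manifest are written there.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = NULL, cohort = cohort_config(),
                       preprocess = preprocess_config(),
                       model = c("both", "opls", "pcalda"),
                       opls = list(n_predictive = NULL, n_orthogonal = 1),
                       pcalda = list(var_explained = 0.95),
                       folds = 10, n_perm = 100, seed = 1, outdir = NULL) {
  model <- match.arg(model)
  if (is.null(seed)) stop("a seed is mandatory")
  structure(
    list(input = input, cohort = cohort, preprocess = preprocess,
         model = model, opls = opls, pcalda = pcalda, folds = folds,
         n_perm = n_perm, seed = as.integer(seed), outdir = outdir),
    class = "run_config"
  )
}

#' Read a run configuration from JSON or YAML
#'
#' Scalar fields override the defaults of [run_config()],
#' [cohort_config()] and [preprocess_config()]; unknown fields are
#' rejected.
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  take <- function(lst, fn, defaults) {
    bad <- setdiff(names(lst), names(formals(fn)))
    if (length(bad)) stop(sprintf("unknown config field(s): %s",
                                  paste(bad, collapse = ", ")))
    do.call(fn, utils::modifyList(defaults, lst))
  }
  cohort <- take(raw$cohort %||% list(), cohort_config, list())
  prep <- take(raw$preprocess %||% list(), preprocess_config, list())
  run_config(
    input = raw$input, cohort = cohort, preprocess = prep,
    model = raw$model %||% "both",
    opls = raw$opls %||% list(n_predictive = NULL, n_orthogonal = 1),
    pcalda = raw$pcalda %||% list(var_explained = 0.95),
    folds = raw$folds %||% 10, n_perm = raw$n_perm %||% 100,
    seed = raw$seed %||% stop("config must set a seed"),
    outdir = raw$outdir
  )
}

#' Run the full serum-SERS analysis pipeline
#'
#' Executes simulate (when no input file is given) -> preprocess -> model
#' fitting -> validation -> reporting. Validation comprises stratified
#' k-fold CV with pooled-confusion metrics and one-vs-rest AUC, training
#' -set reports, score-plot tables, peak ANOVA, and (for OPLS) the
#' permutation validity test. A manifest recording inputs, parameters,
#' seeds and package version makes any run reproducible; reruns under the
#' same config are identical.
#'
#' @param config a [run_config()].
#' @return a result bundle (list): `spectra_raw`, `spectra`, `truth`
#'   (when simulated), per-model `models`, `cv`, `training_report`,
#'   `scores_plot`, `roc`, `permutation` (OPLS), `peaks`, `summary` and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  truth <- NULL
  if (is.null(config$input)) {
    sim <- generate_cohort(config$cohort)
    raw <- sim$spectra
    truth <- sim$truth
    say("simulate: %d samples, seed %d", nrow(raw$intensities),
        config$cohort$seed)
  } else {
    raw <- read_spectrumset(config$input)
    say("load: %s (%d samples)", config$input, nrow(raw$intensities))
  }

  proc <- preprocess_pipeline(raw, config$preprocess)
  say("preprocess: SG(window %d, order %d) + airPLS(lambda %g) + %s",
      config$preprocess$sg_window, config$preprocess$sg_polyorder,
      config$preprocess$airpls_lambda,
      if (config$preprocess$normalize) "vector norm" else "no norm")

  models <- list()
  cv <- list()
  training <- list()
  roc <- list()
  which_models <- if (config$model == "both") c("opls", "pcalda") else
    config$model

  for (m in which_models) {
    spec <- if (m == "opls") c(list(model = "opls"), config$opls) else
      c(list(model = "pcalda"), config$pcalda)
    fit <- fit_classifier(proc$intensities, proc$labels, spec)
    pred_train <- predict_classifier(fit, proc$intensities)
    rep_train <- confusion_metrics(proc$labels, pred_train$labels,
                                   levels(proc$labels))
    rep_train$auc <- one_vs_rest_auc(pred_train$scores, proc$labels)
    cv_m <- kfold_cv(proc$intensities, proc$labels, spec,
                     folds = config$folds, seed = config$seed)
    models[[m]] <- fit
    training[[m]] <- rep_train
    cv[[m]] <- cv_m
    roc[[m]] <- lapply(stats::setNames(nm = levels(proc$labels)),
                       function(cl) {
                         roc_auc(pred_train$scores[, cl], proc$labels == cl)
                       })
    say("%s: CV accuracy %.1f%%, training accuracy %.1f%%",
        m, cv_m$report$accuracy, rep_train$accuracy)
  }

  scores_plot <- NULL
  permutation <- NULL
  if ("opls" %in% which_models) {
    q2fit <- fit_opls(proc$intensities, proc$labels,
                      n_predictive = config$opls$n_predictive,
                      n_orthogonal = config$opls$n_orthogonal %||% 1,
                      cv_folds = config$folds, seed = config$seed)
    models$opls_cv_stats <- list(r2x_cum = q2fit$r2x_cum,
                                 r2y_cum = q2fit$r2y_cum,
                                 q2_cum = q2fit$q2_cum)
    scores_plot <- scores_for_plot(q2fit)
    say("opls fit statistics: R2X %.3f R2Y %.3f Q2 %.3f",
        q2fit$r2x_cum, q2fit$r2y_cum, q2fit$q2_cum)
    if (config$n_perm >= 2) {
      permutation <- permutation_test(
        proc$intensities, proc$labels,
        model_spec = c(config$opls, list(cv_folds = config$folds)),
        n_perm = config$n_perm, seed = config$seed)
      say("permutation: R2 intercept %.3f, Q2 intercept %.3f (%s)",
          permutation$r2_intercept, permutation$q2_intercept,
          if (permutation$well_constructed) "well-constructed"
          else "not well-constructed")
    }
  }

  peaks <- anova_peaks(proc,
                       peaks = if (is.null(config$input))
                         config$cohort$bands else default_serum_bands())
  say("peaks: %d/%d significant at alpha %.2f", sum(peaks$significant),
      nrow(peaks), attr(peaks, "alpha"))

  summary_tab <- do.call(rbind, lapply(which_models, function(m) {
    data.frame(model = m,
               cv_accuracy = cv[[m]]$report$accuracy,
               training_accuracy = training[[m]]$accuracy,
               min_cv_auc = min(cv[[m]]$report$auc),
               stringsAsFactors = FALSE)
  }))

  manifest <- list(
    package = "sersdx",
    version = as.character(utils::packageVersion("sersdx")),
    timestamp = format(Sys.time(), tz = "UTC"),
    input = config$input %||% "simulated",
    seed = config$seed,
    folds = config$folds,
    n_perm = config$n_perm,
    model = config$model,
    preprocess = unclass(config$preprocess),
    opls = config$opls,
    pcalda = config$pcalda,
    cohort_seed = if (is.null(config$input)) config$cohort$seed else NULL,
    log = log_lines
  )

  bundle <- list(spectra_raw = raw, spectra = proc, truth = truth,
                 models = models, cv = cv, training_report = training,
                 scores_plot = scores_plot, roc = roc,
                 permutation = permutation, peaks = peaks,
                 summary = summary_tab, manifest = manifest)

  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

# Persist a result bundle as plain-text tables + a JSON manifest.
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_spectrumset(bundle$spectra, file.path(outdir, "spectra_processed.csv"))
  utils::write.csv(bundle$peaks, file.path(outdir, "peak_table.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$summary, file.path(outdir, "model_summary.csv"),
                   row.names = FALSE)
  for (m in names(bundle$cv)) {
    utils::write.csv(as.data.frame(bundle$cv[[m]]$report$confusion),
                     file.path(outdir, sprintf("cv_confusion_%s.csv", m)),
                     row.names = FALSE)
  }
  if (!is.null(bundle$scores_plot)) {
    utils::write.csv(bundle$scores_plot$scores,
                     file.path(outdir, "opls_scores.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$permutation)) {
    perm <- bundle$permutation
    utils::write.csv(
      data.frame(correlation = perm$correlation, r2y = perm$r2y,
                 q2 = perm$q2),
      file.path(outdir, "permutation_points.csv"), row.names = FALSE)
  }
  for (m in names(bundle$roc)) {
    for (cl in names(bundle$roc[[m]])) {
      utils::write.csv(bundle$roc[[m]][[cl]]$roc,
                       file.path(outdir, sprintf("roc_%s_%s.csv", m, cl)),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
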