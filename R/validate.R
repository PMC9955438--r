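#' Confusion matrix and diagnostic metrics
#'
#' Builds the class-ordered confusion matrix (rows = true class, columns
#' = predicted class) and the diagnostic metrics used for multiclass
#' serum classification:
#' * sensitivity(c) = correctly classified samples of class c / n(c);
#' * specificity(c), diagnostic-table convention: the fraction of
#'   out-of-class samples that were assigned to *their own* correct class,
#'   `sum_(k != c) correct(k) / sum_(k != c) n(k)`;
#' * the standard one-vs-rest specificity TN / (TN + FP), reported
#'   alongside under `specificity_standard`;
#' * overall accuracy = trace / total.
#' Percent values are reported at one decimal (half-up).
#'
#' @param true true class labels.
#' @param predicted predicted class labels.
#' @param class_order character vector fixing row/column order; defaults
#'   to the union of levels.
#' @return an object of class `classification_report` with fields
#'   `confusion`, `sensitivity`, `specificity`, `specificity_standard`
#'   (all percent, 1 decimal), `accuracy` (percent, 1 decimal), raw
#'   fractions under `raw`, and `auc` (NULL until filled by a caller with
#'   continuous scores).
#' @export
confusion_metrics <- function(true, predicted, class_order = NULL) {
  if (length(true) != length(predicted)) {
    stop("label sequences must have equal length")
  }
  if (is.null(class_order)) {
    class_order <- union(levels(as.factor(true)), levels(as.factor(predicted)))
  }
  bad <- setdiff(unique(c(as.character(true), as.character(predicted))),
                 class_order)
  if (length(bad)) {
    stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  }
  true <- factor(as.character(true), levels = class_order)
  predicted <- factor(as.character(predicted), levels = class_order)
  cm <- table(true = true, predicted = predicted)
  cm <- matrix(as.integer(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
  n_c <- rowSums(cm)
  correct <- diag(cm)
  total <- sum(cm)

  sens <- correct / n_c
  spec_paper <- vapply(seq_along(class_order), function(c) {
    sum(correct[-c]) / sum(n_c[-c])
  }, 0)
  spec_std <- vapply(seq_along(class_order), function(c) {
    tn <- total - sum(cm[c, ]) - sum(cm[, c]) + cm[c, c]
    fp <- sum(cm[, c]) - cm[c, c]
    tn / (tn + fp)
  }, 0)
  acc <- sum(correct) / total
  names(spec_paper) <- names(spec_std) <- class_order

  structure(
    list(confusion = cm,
         class_order = class_order,
         sensitivity = pct1(sens),
         specificity = pct1(spec_paper),
         specificity_standard = pct1(spec_std),
         accuracy = pct1(acc),
         raw = list(sensitivity = sens, specificity = spec_paper,
                    specificity_standard = spec_std, accuracy = acc),
         auc = NULL),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  cat("sensitivity (%):", paste(sprintf("%s %.1f", names(x$sensitivity),
                                        x$sensitivity), collapse = ", "), "\n")
  cat("specificity (%):", paste(sprintf("%s %.1f", names(x$specificity),
                                        x$specificity), collapse = ", "), "\n")
  cat(sprintf("accuracy: %.1f%%\n", x$accuracy))
  if (!is.null(x$auc)) {
    cat("AUC:", paste(sprintf("%s %.3f", names(x$auc), x$auc),
                      collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reconstruct a binary confusion report from printed rates
#'
#' Given per-class sensitivity and specificity in percent and the two
#' group sizes, reconstructs the integer correct counts (nearest integer)
#' and recomputes the full report, which allows checking the internal
#' consistency of published binary summary tables.
#'
#' @param sensitivity_pct,specificity_pct printed percent rates.
#' @param n_pos,n_neg positive (case) and negative (control) group sizes.
#' @param classes length-2 character vector naming positive and negative
#'   class.
#' @return a `classification_report` for the reconstructed counts.
#' @export
report_from_rates <- function(sensitivity_pct, specificity_pct,
                              n_pos, n_neg,
                              classes = c("case", "control")) {
  tp <- round(sensitivity_pct / 100 * n_pos)
  tn <- round(specificity_pct / 100 * n_neg)
  true <- rep(classes, c(n_pos, n_neg))
  pred <- c(rep(classes, c(tp, n_pos - tp)),
            rep(rev(classes), c(tn, n_neg - tn)))
  confusion_metrics(true, pred, class_order = classes)
}

# Internal fit/predict dispatch shared by kfold_cv and run_pipeline.
fit_classifier <- function(X, labels, spec) {
  model <- spec$model %||% "opls"
  if (model == "opls") {
    classes <- levels(as.factor(labels))
    n_pred <- spec$n_predictive %||% (length(classes) - 1L)
    n_orth <- spec$n_orthogonal %||% 0L
    core <- opls_core(X, dummy_response(labels), n_pred, n_orth,
                      scale = isTRUE(spec$scale))
    structure(c(core, list(class_labels = classes,
                           labels = as.factor(labels))),
              class = "opls_model")
  } else if (model == "pcalda") {
    fit_pcalda(X, labels,
               var_explained = spec$var_explained %||% 0.95,
               n_components = spec$n_components)
  } else {
    stop(sprintf("unknown model '%s' (use 'opls' or 'pcalda')", model))
  }
}

predict_classifier <- function(fit, X) {
  if (inherits(fit, "opls_model")) predict_opls(fit, X) else
    predict_pcalda(fit, X)
}

#' Stratified k-fold cross-validated classification
#'
#' Splits the cohort into stratified folds (reproducible from `seed`),
#' refits the requested classifier on each training portion and predicts
#' the held-out samples, so every sample is predicted exactly once
#' out-of-fold. The pooled predictions are summarised in a
#' [confusion_metrics()] report with one-vs-rest AUCs from the pooled
#' continuous class scores.
#'
#' @param x matrix or [spectrum_set()].
#' @param labels class labels (ignored for a `spectrum_set`).
#' @param model_spec list: `model` ("opls" or "pcalda") plus model
#'   parameters (`n_predictive`, `n_orthogonal`, `n_components`, ...).
#' @param folds number of folds; must not exceed the smallest class.
#' @param seed integer seed for the split.
#' @return list with `predictions` (factor, original sample order),
#'   `scores` (pooled continuous class scores), `fold_id` and `report`.
#' @export
kfold_cv <- function(x, labels = NULL, model_spec = list(model = "opls"),
                     folds = 10, seed = 1) {
  d <- as_xy(x, labels)
  X <- d$X; labels <- d$labels
  fold_id <- stratified_folds(labels, folds, seed)
  classes <- levels(labels)
  pred <- factor(rep(NA_character_, length(labels)), levels = classes)
  scores <- matrix(NA_real_, length(labels), length(classes),
                   dimnames = list(NULL, classes))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- fit_classifier(X[tr, , drop = FALSE], droplevels(labels[tr]),
                          model_spec)
    out <- predict_classifier(fit, X[!tr, , drop = FALSE])
    pred[!tr] <- factor(as.character(out$labels), levels = classes)
    scores[!tr, colnames(out$scores)] <- out$scores
  }
  report <- confusion_metrics(labels, pred, classes)
  report$auc <- one_vs_rest_auc(scores, labels)
  list(predictions = pred, scores = scores, fold_id = fold_id,
       report = report)
}

#' Rank-statistic ROC curve and AUC
#'
#' AUC is computed as the normalized Mann-Whitney rank statistic (tied
#' scores contribute 1/2), equivalent to the probability that a random
#' positive sample outranks a random negative one; it is invariant under
#' strictly monotone transforms of the scores. ROC points are produced at
#' every distinct score threshold.
#'
#' @param scores numeric vector of continuous class scores (higher =
#'   more positive).
#' @param membership logical (or 0/1) vector: TRUE for the positive
#'   class.
#' @return list with `auc` and `roc` (data.frame of threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, membership) {
  membership <- as.logical(membership)
  if (length(scores) != length(membership)) stop("length mismatch")
  n_pos <- sum(membership); n_neg <- sum(!membership)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve")
  }
  r <- rank(scores)
  auc <- (sum(r[membership]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores[!membership] >= t) / n_neg, 0),
    tpr = vapply(thr, function(t) sum(scores[membership] >= t) / n_pos, 0)
  )
  list(auc = auc, roc = roc)
}

#' One-vs-rest AUC per class
#'
#' @param scores matrix of continuous class scores (columns named by
#'   class).
#' @param labels true class labels.
#' @return named numeric vector of per-class AUCs.
#' @export
one_vs_rest_auc <- function(scores, labels) {
  labels <- as.factor(labels)
  vapply(colnames(scores), function(cl) {
    roc_auc(scores[, cl], labels == cl)$auc
  }, 0)
}

#' Permutation validation of an OPLS-DA model
#'
#' Refits the model `n_perm` times with the rows of the dummy response
#' randomly permuted, recording for each permutation the mean absolute
#' column-wise Pearson correlation between permuted and original response
#' (the abscissa), R2Y(cum) and Q2(cum). Least-squares lines of R2Y and
#' Q2 against the abscissa — including the original model at correlation
#' 1 — give the intercepts used as overfitting diagnostics; the model is
#' flagged well-constructed when the R2 intercept is below 0.4 and the Q2
#' intercept below 0.05.
#'
#' @param x matrix or [spectrum_set()].
#' @param labels class labels (ignored for a `spectrum_set`).
#' @param model_spec list of OPLS settings (`n_predictive`,
#'   `n_orthogonal`, `cv_folds`).
#' @param n_perm number of permutations (>= 2; 100 by convention).
#' @param seed integer seed driving the permutations and CV splits.
#' @return an object of class `permutation_result`: per-permutation
#'   `correlation`, `r2y`, `q2`; `r2_intercept`, `q2_intercept`;
#'   the original model's `r2y` / `q2`; and `well_constructed`.
#' @export
permutation_test <- function(x, labels = NULL,
                             model_spec = list(), n_perm = 100, seed = 1) {
  if (n_perm < 2) stop("n_perm must be >= 2")
  d <- as_xy(x, labels)
  X <- d$X; labels <- d$labels
  classes <- levels(labels)
  n_pred <- model_spec$n_predictive %||% (length(classes) - 1L)
  n_orth <- model_spec$n_orthogonal %||% 0L
  folds <- model_spec$cv_folds %||% 10L

  orig <- fit_opls(X, labels, n_pred, n_orth, cv_folds = folds, seed = seed)
  Y <- dummy_response(labels)

  perm_seeds <- with_seed(seed, sample.int(2^31 - 2, n_perm))
  res <- matrix(NA_real_, n_perm, 3,
                dimnames = list(NULL, c("correlation", "r2y", "q2")))
  for (i in seq_len(n_perm)) {
    ord <- with_seed(perm_seeds[i], sample.int(nrow(X)))
    lab_p <- labels[ord]
    cors <- vapply(seq_len(ncol(Y)),
                   function(j) abs(stats::cor(Y[ord, j], Y[, j])), 0)
    fit <- fit_opls(X, lab_p, n_pred, n_orth, cv_folds = folds,
                    seed = perm_seeds[i])
    res[i, ] <- c(mean(cors), fit$r2y_cum, fit$q2_cum)
  }
  absc <- c(res[, "correlation"], 1)
  r2_line <- stats::lm(c(res[, "r2y"], orig$r2y_cum) ~ absc)
  q2_line <- stats::lm(c(res[, "q2"], orig$q2_cum) ~ absc)
  r2_int <- unname(stats::coef(r2_line)[1])
  q2_int <- unname(stats::coef(q2_line)[1])
  structure(
    list(correlation = res[, "correlation"], r2y = res[, "r2y"],
         q2 = res[, "q2"],
         r2_intercept = r2_int, q2_intercept = q2_int,
         original_r2y = orig$r2y_cum, original_q2 = orig$q2_cum,
         n_perm = n_perm, seed = seed,
         well_constructed = permutation_verdict(r2_int, q2_int)),
    class = "permutation_result"
  )
}

#' Permutation-test validity verdict
#'
#' A model is considered well-constructed when the permutation-regression
#' R2 intercept is below 0.4 and the Q2 intercept below 0.05.
#'
#' @param r2_intercept,q2_intercept regression intercepts at correlation
#'   zero.
#' @return logical.
#' @export
permutation_verdict <- function(r2_intercept, q2_intercept) {
  (r2_intercept < 0.4) && (q2_intercept < 0.05)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: %d permutations\nR2 intercept = %.3f, Q2 intercept = %.3f -> %s\n",
    x$n_perm, x$r2_intercept, x$q2_intercept,
    if (x$well_constructed) "well-constructed" else "NOT well-constructed"))
  invisible(x)
}
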