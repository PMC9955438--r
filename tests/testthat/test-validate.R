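test_that("confusion metrics: perfect classification scores 100 everywhere", {
  lab <- factor(rep(c("healthy", "stone", "polyp"), c(6, 5, 4)),
                levels = c("healthy", "stone", "polyp"))
  rep0 <- confusion_metrics(lab, lab, levels(lab))
  expect_equal(unname(rep0$sensitivity), rep(100, 3))
  expect_equal(unname(rep0$specificity), rep(100, 3))
  expect_equal(unname(rep0$specificity_standard), rep(100, 3))
  expect_equal(rep0$accuracy, 100)
  expect_equal(diag(rep0$confusion), c(healthy = 6L, stone = 5L, polyp = 4L))
})

test_that("confusion metrics invariants: row sums, trace accuracy, order invariance", {
  set.seed(50)
  classes <- c("healthy", "stone", "polyp")
  true <- factor(sample(classes, 60, TRUE), levels = classes)
  pred <- factor(sample(classes, 60, TRUE), levels = classes)
  r <- confusion_metrics(true, pred, classes)
  expect_equal(unname(rowSums(r$confusion)), as.vector(table(true)))
  expect_equal(r$raw$accuracy, sum(diag(r$confusion)) / 60)
  # reordering the samples leaves the report unchanged
  ord <- sample(60)
  r2 <- confusion_metrics(true[ord], pred[ord], classes)
  expect_identical(r$confusion, r2$confusion)
  expect_error(confusion_metrics(true, factor(rep("x", 60)), classes),
               "unknown")
  expect_error(confusion_metrics(true, pred[1:10]), "equal length")
})

test_that("binary reports reconstructed from printed rates are consistent", {
  r <- report_from_rates(98, 88, 51, 25, c("stone", "polyp"))
  expect_equal(unname(r$sensitivity[1]), 98.0)
  expect_equal(unname(r$specificity_standard[1]), 88.0)
  expect_equal(unname(rowSums(r$confusion)), c(51, 25))
})

test_that("k-fold CV predicts each sample exactly once, out of fold", {
  sim <- small_cohort(seed = 51)
  proc <- preprocess_pipeline(sim$spectra)
  cv <- kfold_cv(proc, model_spec = list(model = "opls", n_orthogonal = 1),
                 folds = 5, seed = 51)
  expect_false(any(is.na(cv$predictions)))
  expect_false(any(is.na(cv$scores)))
  expect_equal(sort(unique(cv$fold_id)), 1:5)
  # stratification: every fold contains every class
  expect_true(all(table(cv$fold_id, proc$labels) > 0))
  # reproducible from the seed
  cv2 <- kfold_cv(proc, model_spec = list(model = "opls", n_orthogonal = 1),
                  folds = 5, seed = 51)
  expect_identical(cv$predictions, cv2$predictions)
  expect_error(kfold_cv(proc, folds = 11), "smallest class")
})

test_that("CV accuracy is high for strong effects and chance-level when permuted", {
  sim <- small_cohort(seed = 52, effect_scale = 2)
  proc <- preprocess_pipeline(sim$spectra)
  cv <- kfold_cv(proc, model_spec = list(model = "opls", n_orthogonal = 1),
                 folds = 5, seed = 52)
  expect_gte(cv$report$accuracy, 95)
  set.seed(520)
  acc_p <- replicate(3, {
    lab_p <- sample(proc$labels)
    kfold_cv(proc$intensities, lab_p,
             model_spec = list(model = "opls", n_orthogonal = 0),
             folds = 5, seed = 52)$report$accuracy
  })
  chance <- 100 * max(table(proc$labels)) / length(proc$labels)
  expect_lte(abs(mean(acc_p) - chance), 10)
})

test_that("PCA-LDA CV accuracy is reported next to OPLS-DA (soft comparison)", {
  sim <- small_cohort(seed = 53)
  proc <- preprocess_pipeline(sim$spectra)
  acc_opls <- kfold_cv(proc, model_spec = list(model = "opls",
                                               n_orthogonal = 1),
                       folds = 5, seed = 53)$report$accuracy
  acc_pcalda <- kfold_cv(proc, model_spec = list(model = "pcalda"),
                         folds = 5, seed = 53)$report$accuracy
  # tendency only; both must at least be well above chance here
  expect_gte(acc_opls, 70)
  expect_gte(acc_pcalda, 70)
  succeed(sprintf("CV accuracy: OPLS-DA %.1f%%, PCA-LDA %.1f%%",
                  acc_opls, acc_pcalda))
})

test_that("rank-statistic AUC matches pair counting and its edge cases", {
  # perfectly separated
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))$auc, 1)
  # all scores identical
  expect_equal(roc_auc(rep(2, 8), rep(c(TRUE, FALSE), 4))$auc, 0.5)
  # 6-sample list with ties vs brute-force pair counting
  s <- c(0.1, 0.4, 0.4, 0.35, 0.8, 0.7)
  m <- c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE)
  expect_equal(roc_auc(s, m)$auc, oracle_auc_pairs(s, m))
  set.seed(54)
  s2 <- sample(round(runif(30), 1)); m2 <- runif(30) > 0.5
  expect_equal(roc_auc(s2, m2)$auc, oracle_auc_pairs(s2, m2))
  # invariant under strictly monotone transforms
  expect_equal(roc_auc(exp(3 * s2), m2)$auc, roc_auc(s2, m2)$auc)
  expect_error(roc_auc(s2, rep(TRUE, 30)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  s <- rnorm(40); m <- c(rep(TRUE, 15), rep(FALSE, 25))
  s[m] <- s[m] + 1
  ref <- as.numeric(pROC::auc(pROC::roc(m, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, m)$auc, ref, tolerance = 1e-10)
})

test_that("ROC point list starts at (0,0) and ends at (1,1)", {
  set.seed(56)
  s <- rnorm(25); m <- runif(25) > 0.4
  roc <- roc_auc(s, m)$roc
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})

test_that("permutation verdict applies the published thresholds", {
  expect_true(permutation_verdict(0.16, -0.388))
  expect_false(permutation_verdict(0.50, 0.20))
  expect_false(permutation_verdict(0.39, 0.20))
  expect_false(permutation_verdict(0.50, -0.1))
  expect_true(permutation_verdict(0.39, 0.049))
})

test_that("permutation test separates a real model from its null", {
  sim <- small_cohort(seed = 57, effect_scale = 1.5)
  proc <- preprocess_pipeline(sim$spectra)
  pt <- permutation_test(proc, model_spec = list(n_orthogonal = 0,
                                                 cv_folds = 5),
                         n_perm = 30, seed = 57)
  expect_length(pt$q2, 30)
  expect_gt(pt$original_q2, max(pt$q2))
  expect_true(pt$well_constructed)
  # permuted-label correlations live strictly below the original's 1
  expect_true(all(pt$correlation < 1))
  expect_error(permutation_test(proc, n_perm = 1), ">= 2")
})
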