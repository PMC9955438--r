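test_that("with no orthogonal components OPLS equals plain NIPALS PLS", {
  d <- two_clouds(n_per = 6, p = 5, sep = 4, seed = 20)
  m <- fit_opls(d$X, d$labels, n_predictive = 1, n_orthogonal = 0,
                cv_folds = 3, seed = 1)
  oracle <- oracle_pls1_binary(d$X, d$labels)
  # scores/weights defined up to sign
  s <- sign(sum(m$weights[, 1] * oracle$w))
  expect_equal(unname(m$weights[, 1]) * s, oracle$w, tolerance = 1e-8)
  expect_equal(unname(m$scores[, 1]) * s, oracle$t, tolerance = 1e-8)
  expect_equal(unname(m$loadings[, 1]) * s, oracle$p, tolerance = 1e-8)
})

test_that("Q2 matches a brute-force fold-refit PRESS oracle", {
  set.seed(21)
  X <- matrix(rnorm(8 * 5), 8, 5)
  X[5:8, 1:2] <- X[5:8, 1:2] + 2
  labels <- factor(rep(c("a", "b"), each = 4))
  folds <- 4  # leave-one-out per class pair (fold size 2)
  m <- fit_opls(X, labels, n_predictive = 1, n_orthogonal = 0,
                cv_folds = folds, seed = 3)
  fold_id <- sersdx:::stratified_folds(labels, folds, seed = 3)
  expect_equal(m$q2_cum, oracle_q2_folds(X, labels, fold_id),
               tolerance = 1e-8)
})

test_that("deflation conserves the X sum of squares", {
  sim <- small_cohort(seed = 22)
  proc <- preprocess_pipeline(sim$spectra)
  m <- fit_opls(proc, n_predictive = 2, n_orthogonal = 2, cv_folds = 5)
  Xc <- sweep(proc$intensities, 2, m$x_mean)
  ssx0 <- sum(Xc^2)
  explained <- sum(tcrossprod(m$scores, m$loadings)^2) +
    sum(tcrossprod(m$ortho_scores, m$ortho_loadings)^2)
  Xhat <- tcrossprod(m$scores, m$loadings) +
    tcrossprod(m$ortho_scores, m$ortho_loadings)
  residual <- sum((Xc - Xhat)^2)
  expect_equal(explained + residual, ssx0, tolerance = 1e-6 * ssx0)
  expect_equal(m$r2x_cum, explained / ssx0, tolerance = 1e-6)
})

test_that("orthogonal scores are uncorrelated with the dummy response", {
  sim <- small_cohort(seed = 23, noise_sd = 0)
  proc <- preprocess_pipeline(sim$spectra)
  m <- fit_opls(proc, n_orthogonal = 2, cv_folds = 5)
  Y <- sersdx:::dummy_response(proc$labels)
  for (k in seq_len(ncol(m$ortho_scores))) {
    for (j in seq_len(ncol(Y))) {
      expect_lt(abs(cor(m$ortho_scores[, k], Y[, j])), 1e-6)
    }
  }
})

test_that("R2Y(cum) is non-decreasing in the predictive component count", {
  sim <- small_cohort(seed = 24)
  proc <- preprocess_pipeline(sim$spectra)
  r2 <- vapply(1:2, function(a) {
    fit_opls(proc, n_predictive = a, n_orthogonal = 1,
             cv_folds = 5)$r2y_cum
  }, 0)
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("permuted labels give chance-level Q2", {
  sim <- small_cohort(seed = 25, effect_scale = 2)
  proc <- preprocess_pipeline(sim$spectra)
  set.seed(250)
  q2 <- replicate(10, {
    lab <- sample(proc$labels)
    fit_opls(proc$intensities, lab, n_predictive = 2, n_orthogonal = 0,
             cv_folds = 5, seed = sample.int(1e6, 1))$q2_cum
  })
  expect_gte(mean(q2 <= 0.05), 0.9)
})

test_that("prediction recovers a separable training set and is reproducible", {
  d <- two_clouds(n_per = 8, p = 6, sep = 10, seed = 26)
  m <- fit_opls(d$X, d$labels, n_predictive = 1, n_orthogonal = 1,
                cv_folds = 4, seed = 1)
  pred <- predict_opls(m, d$X)
  expect_equal(as.character(pred$labels), as.character(d$labels))
  # a single spectrum equal to a training row gives the in-fit scores
  one <- predict_opls(m, d$X[3, , drop = FALSE])
  expect_equal(one$scores[1, ], pred$scores[3, ], tolerance = 1e-12)
  # dummy-coded class scores sum to ~1 per sample
  expect_equal(unname(rowSums(pred$scores)), rep(1, nrow(d$X)),
               tolerance = 1e-8)
})

test_that("prediction validates dimensions", {
  d <- two_clouds(seed = 27)
  m <- fit_opls(d$X, d$labels, n_predictive = 1, cv_folds = 4)
  expect_error(predict_opls(m, matrix(0, 2, 3)), "variables")
})

test_that("fit errors on invalid settings", {
  d <- two_clouds(n_per = 5, seed = 28)
  expect_error(fit_opls(d$X, d$labels, n_orthogonal = -1), ">= 0")
  expect_error(fit_opls(d$X, d$labels, cv_folds = 6), "smallest class")
  expect_error(fit_opls(matrix(1, 10, 4), d$labels, cv_folds = 3),
               "degenerate|variance")
  tiny <- factor(c("a", "a", "a", "b", "b",
                   rep("a", 5)))  # class b has 2 samples
  expect_error(fit_opls(two_clouds(n_per = 5, seed = 1)$X, tiny,
                        cv_folds = 2), "3 samples")
})

test_that("score-plot export: rows, separation, ellipse coverage", {
  sim <- generate_cohort(cohort_config(seed = 29))
  proc <- preprocess_pipeline(sim$spectra)
  m <- fit_opls(proc, n_orthogonal = 1, cv_folds = 10, seed = 29)
  sp <- scores_for_plot(m)
  expect_equal(nrow(sp$scores), 148)
  t1 <- sp$scores$t1; t2 <- sp$scores$t2
  inside <- (t1 / sp$ellipse$semi_axes[1])^2 +
    (t2 / sp$ellipse$semi_axes[2])^2 <= 1
  expect_gte(mean(inside), 0.93)
  # between-class centroid separation exceeds mean within-class spread
  sc <- cbind(t1, t2)
  cents <- rowsum(sc, sp$scores$label) / as.vector(table(sp$scores$label))
  d_between <- mean(dist(cents))
  d_within <- mean(sqrt(rowSums((sc - cents[sp$scores$label, ])^2)))
  expect_gt(d_between, d_within)
  # fewer than 2 total components is an error
  m1 <- fit_opls(two_clouds(seed = 1)$X, two_clouds(seed = 1)$labels,
                 n_predictive = 1, n_orthogonal = 0, cv_folds = 4)
  expect_error(scores_for_plot(m1), "2 components")
})

test_that("first predictive loading of a binary model recovers its effect bands", {
  sim <- generate_cohort(cohort_config(seed = 30))
  proc <- preprocess_pipeline(sim$spectra)
  keep <- proc$labels %in% c("healthy", "stone")
  m <- fit_opls(proc$intensities[keep, ], droplevels(proc$labels[keep]),
                n_predictive = 1, n_orthogonal = 1, cv_folds = 10, seed = 30)
  top <- proc$wavenumbers[order(abs(m$loadings[, 1]),
                                decreasing = TRUE)[1:40]]
  for (b in c(637, 722, 888, 1203, 1652)) {
    expect_lte(min(abs(top - b)), 8)
  }
})
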