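#' Principal component analysis of a spectral matrix
#'
#' Centered singular-value decomposition; returns scores, orthonormal
#' loadings and explained-variance fractions.
#'
#' @param x numeric matrix (samples x variables) or [spectrum_set()].
#' @param n_components number of components to keep; must not exceed
#'   `min(samples - 1, variables)`.
#' @return list with `mean`, `loadings`, `scores`,
#'   `explained_variance` (fractions, non-increasing) and `n_components`.
#' @export
fit_pca <- function(x, n_components) {
  if (inherits(x, "spectrum_set")) x <- x$intensities
  x <- as.matrix(x)
  max_k <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_k) {
    stop(sprintf("n_components (%d) exceeds min(samples - 1, variables) = %d",
                 n_components, max_k))
  }
  mu <- colMeans(x)
  Xc <- sweep(x, 2, mu)
  sv <- svd(Xc)
  ev <- sv$d^2 / sum(sv$d^2)
  k <- seq_len(n_components)
  list(mean = mu,
       loadings = sv$v[, k, drop = FALSE],
       scores = sweep(sv$u[, k, drop = FALSE], 2, sv$d[k], "*"),
       explained_variance = ev[k],
       n_components = n_components)
}

#' Fisher linear discriminant analysis on PCA scores
#'
#' Linear discriminant analysis with equal class priors (the diagnostic
#' convention) on retained principal-component scores: discriminant
#' directions from the pooled within-class scatter, classification by the
#' maximum posterior under the shared-covariance Gaussian model, which
#' with equal priors is the nearest class mean in the whitened
#' discriminant space.
#'
#' @param scores numeric matrix of retained PC scores.
#' @param labels class labels.
#' @param prior class priors; default equal.
#' @return list with the `MASS::lda` fit (`lda`), class means and
#'   discriminant directions (`scaling`).
#' @export
fit_lda <- function(scores, labels, prior = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("at least 2 classes are required")
  if (is.null(prior)) prior <- rep(1 / nlevels(labels), nlevels(labels))
  fit <- tryCatch(
    MASS::lda(scores, grouping = labels, prior = prior),
    error = function(e) {
      stop(paste0("LDA failed (", conditionMessage(e),
                  "); the within-class scatter may be singular - ",
                  "retain fewer principal components"))
    }
  )
  list(lda = fit, means = fit$means, scaling = fit$scaling, prior = prior)
}

#' Fit the two-stage PCA-LDA classifier
#'
#' PCA reduces the spectral matrix to the smallest number of components
#' explaining at least `var_explained` of the variance (capped at
#' `samples / 3`); Fisher LDA with equal priors is then fitted on the
#' retained scores. LDA never sees the raw high-dimensional spectra.
#'
#' @param x matrix or [spectrum_set()] of preprocessed spectra.
#' @param labels class labels (ignored for a `spectrum_set`).
#' @param var_explained cumulative explained-variance threshold used to
#'   pick the retained component count.
#' @param n_components optional fixed component count (overrides the
#'   threshold rule).
#' @param prior class priors; default equal.
#' @return an object of class `pcalda_model`.
#' @export
fit_pcalda <- function(x, labels = NULL, var_explained = 0.95,
                       n_components = NULL, prior = NULL) {
  d <- as_xy(x, labels)
  X <- d$X; labels <- d$labels
  max_k <- min(nrow(X) - 1L, ncol(X), max(2L, floor(nrow(X) / 3)))
  if (is.null(n_components)) {
    full <- fit_pca(X, min(nrow(X) - 1L, ncol(X)))
    cum <- cumsum(full$explained_variance)
    n_components <- min(which(cum >= var_explained), max_k)
  }
  pca <- fit_pca(X, n_components)
  lda <- fit_lda(pca$scores, labels, prior)
  structure(
    list(pca = pca, lda = lda, class_labels = levels(labels),
         labels = labels, n_components = n_components),
    class = "pcalda_model"
  )
}

#' Predict classes from a PCA-LDA model
#'
#' @param model a `pcalda_model`.
#' @param x_new matrix (or [spectrum_set()]) with the training variable
#'   count.
#' @return list with `labels` (predicted classes) and `scores` (per-class
#'   posterior probabilities under the shared-covariance model).
#' @export
predict_pcalda <- function(model, x_new) {
  if (inherits(x_new, "spectrum_set")) x_new <- x_new$intensities
  x_new <- if (is.null(dim(x_new))) matrix(x_new, nrow = 1) else as.matrix(x_new)
  if (ncol(x_new) != length(model$pca$mean)) {
    stop(sprintf("x_new has %d variables; model was trained on %d",
                 ncol(x_new), length(model$pca$mean)))
  }
  sc <- sweep(x_new, 2, model$pca$mean) %*% model$pca$loadings
  pr <- stats::predict(model$lda$lda, sc)
  list(labels = factor(as.character(pr$class), levels = model$class_labels),
       scores = pr$posterior)
}

#' @export
print.pcalda_model <- function(x, ...) {
  cat(sprintf("pcalda_model: %d PCs (%.1f%% variance), %d classes\n",
              x$n_components,
              100 * sum(x$pca$explained_variance), length(x$class_labels)))
  invisible(x)
}
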