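#' @title Orthogonal PLS discriminant analysis (OPLS-DA)
#' @description Fits a discriminant OPLS model: class labels are dummy
#'   coded (one indicator column per class), X is mean-centered,
#'   `n_orthogonal` components capturing Y-uncorrelated X variation are
#'   extracted and removed, and `n_predictive` NIPALS PLS components are
#'   fitted on the filtered matrix. Model quality is summarised by
#'   R2X(cum), R2Y(cum) and a cross-validated Q2(cum) from stratified
#'   k-fold cross-validation.
#'
#' @details Orthogonal components are found by projecting each candidate
#'   PLS loading off the span of `t(X) %*% Y`, so their scores are exactly
#'   uncorrelated with every dummy-response column. Q2(cum) follows the
#'   cumulative-product convention `1 - prod_a(PRESS_a / SS_(a-1))`, where
#'   `PRESS_a` pools squared out-of-fold dummy-response prediction errors
#'   of the a-component model and `SS_(a-1)` is the response residual sum
#'   of squares after `a - 1` components of the full fit.
#'
#' @param x preprocessed data: numeric matrix (samples x variables) or a
#'   [spectrum_set()].
#' @param labels class labels (ignored when `x` is a `spectrum_set`).
#' @param n_predictive number of predictive components; default is
#'   `nlevels - 1`.
#' @param n_orthogonal number of orthogonal components, or `"auto"` to add
#'   orthogonal components while cross-validated Q2 improves by more than
#'   0.01 (capped at 5).
#' @param cv_folds folds for the Q2 cross-validation (stratified).
#' @param seed seed for the cross-validation split.
#' @param scale logical; unit-variance scale columns in addition to
#'   mean-centering (default `FALSE`, the usual choice for normalized
#'   spectra).
#' @return an object of class `opls_model`.
#' @export
fit_opls <- function(x, labels = NULL, n_predictive = NULL,
                     n_orthogonal = 0, cv_folds = 10, seed = 1,
                     scale = FALSE) {
  d <- as_xy(x, labels)
  X <- d$X; labels <- d$labels
  classes <- levels(labels)
  if (length(classes) < 2) stop("at least 2 classes are required")
  if (min(table(labels)) < 3) stop("at least 3 samples per class are required")
  if (is.null(n_predictive)) n_predictive <- length(classes) - 1L
  if (n_predictive < 1) stop("n_predictive must be >= 1")
  auto_orth <- identical(n_orthogonal, "auto")
  if (!auto_orth && n_orthogonal < 0) stop("n_orthogonal must be >= 0")
  if (cv_folds > min(table(labels))) {
    stop(sprintf("cv_folds (%d) exceeds the smallest class size (%d)",
                 cv_folds, min(table(labels))))
  }

  if (auto_orth) {
    best <- fit_opls(X, labels, n_predictive, 0, cv_folds, seed, scale)
    for (k in seq_len(5)) {
      cand <- fit_opls(X, labels, n_predictive, k, cv_folds, seed, scale)
      if (cand$q2_cum > best$q2_cum + 0.01) best <- cand else break
    }
    return(best)
  }

  core <- opls_core(X, dummy_response(labels), n_predictive, n_orthogonal,
                    scale = scale)
  q2 <- opls_cv_q2(X, labels, n_predictive, n_orthogonal, cv_folds, seed,
                   scale = scale)
  structure(
    c(core,
      list(class_labels = classes, labels = labels,
           q2_cum = q2$q2_cum, q2_per_component = q2$q2_per_component,
           press = q2$press, cv_folds = cv_folds, cv_seed = seed)),
    class = "opls_model"
  )
}

# Dummy (one column per class) response; rows sum to 1.
dummy_response <- function(labels) {
  labels <- as.factor(labels)
  Y <- stats::model.matrix(~ labels - 1)
  colnames(Y) <- levels(labels)
  attr(Y, "assign") <- NULL
  attr(Y, "contrasts") <- NULL
  Y
}

# Accept a matrix + labels or a spectrum_set.
as_xy <- function(x, labels) {
  if (inherits(x, "spectrum_set")) {
    list(X = x$intensities, labels = x$labels)
  } else {
    if (is.null(labels)) stop("labels are required with a matrix input")
    list(X = as.matrix(x), labels = as.factor(labels))
  }
}

# One NIPALS round on current residual matrices; returns w, t, c.
nipals_round <- function(X, Y, max_iter = 500, tol = 1e-12) {
  u <- Y[, which.max(colSums(Y^2))]
  t_old <- NULL
  for (i in seq_len(max_iter)) {
    w <- drop(crossprod(X, u)) / sum(u^2)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) stop("degenerate data: NIPALS weight collapsed to zero")
    w <- w / nw
    tt <- drop(X %*% w)
    cc <- drop(crossprod(Y, tt)) / sum(tt^2)
    u <- drop(Y %*% cc) / sum(cc^2)
    if (!is.null(t_old) && sum((tt - t_old)^2) / sum(tt^2) < tol) break
    t_old <- tt
  }
  list(w = w, t = tt, c = cc)
}

# Deterministic OPLS fit (no CV): centering, orthogonal filtering, NIPALS.
opls_core <- function(X, Y, n_predictive, n_orthogonal, scale = FALSE) {
  X <- as.matrix(X)
  x_mean <- colMeans(X)
  x_scale <- if (scale) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    s
  } else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  y_mean <- colMeans(Y)
  Yc <- sweep(Y, 2, y_mean)
  ssx0 <- sum(Xc^2)
  ssy0 <- sum(Yc^2)
  if (ssx0 == 0) stop("degenerate data: X has no variance")

  p_var <- ncol(Xc)
  Wo <- matrix(0, p_var, 0); Po <- matrix(0, p_var, 0)
  To <- matrix(0, nrow(Xc), 0)
  Xf <- Xc
  for (k in seq_len(n_orthogonal)) {
    nr <- nipals_round(Xf, Yc)
    p_load <- drop(crossprod(Xf, nr$t)) / sum(nr$t^2)
    # basis of the Y-predictive weight space of the current residual X
    WY <- crossprod(Xf, Yc)
    sv <- svd(WY)
    keep <- sv$d > max(sv$d) * 1e-10
    basis <- sv$u[, keep, drop = FALSE]
    wo <- p_load - basis %*% crossprod(basis, p_load)
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) {
      stop("no orthogonal variation left to extract; reduce n_orthogonal")
    }
    wo <- drop(wo) / nwo
    to <- drop(Xf %*% wo)
    po <- drop(crossprod(Xf, to)) / sum(to^2)
    Xf <- Xf - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }

  W <- matrix(0, p_var, 0); P <- matrix(0, p_var, 0)
  Tm <- matrix(0, nrow(Xf), 0); C <- matrix(0, ncol(Yc), 0)
  Xr <- Xf; Yr <- Yc
  ssy_path <- ssy0  # residual Y SS after 0..A components
  for (a in seq_len(n_predictive)) {
    nr <- nipals_round(Xr, Yr)
    p_load <- drop(crossprod(Xr, nr$t)) / sum(nr$t^2)
    Xr <- Xr - tcrossprod(nr$t, p_load)
    Yr <- Yr - tcrossprod(nr$t, nr$c)
    W <- cbind(W, nr$w); P <- cbind(P, p_load)
    Tm <- cbind(Tm, nr$t); C <- cbind(C, nr$c)
    ssy_path <- c(ssy_path, sum(Yr^2))
  }

  r2x <- 1 - (sum(Xr^2)) / ssx0
  r2y <- 1 - sum(Yr^2) / ssy0
  list(
    x_mean = x_mean, x_scale = x_scale, y_mean = y_mean, scaled = scale,
    weights = W, loadings = P, scores = Tm, y_loadings = C,
    ortho_weights = Wo, ortho_loadings = Po, ortho_scores = To,
    r2x_cum = r2x, r2y_cum = r2y, ssy_path = ssy_path,
    n_predictive = n_predictive, n_orthogonal = n_orthogonal
  )
}

# Filter new (already centered/scaled) data with stored orthogonal
# components, then return predictive scores per component count.
opls_filter <- function(core, Xc) {
  if (core$n_orthogonal > 0) {
    for (k in seq_len(core$n_orthogonal)) {
      to <- drop(Xc %*% core$ortho_weights[, k])
      Xc <- Xc - tcrossprod(to, core$ortho_loadings[, k])
    }
  }
  Xc
}

# Predictive scores of filtered data, sequential deflation.
opls_scores_seq <- function(core, Xf) {
  A <- core$n_predictive
  Tm <- matrix(0, nrow(Xf), A)
  Xr <- Xf
  for (a in seq_len(A)) {
    Tm[, a] <- drop(Xr %*% core$weights[, a])
    Xr <- Xr - tcrossprod(Tm[, a], core$loadings[, a])
  }
  Tm
}

# Stratified k-fold CV Q2 under the cumulative-product convention.
opls_cv_q2 <- function(X, labels, n_predictive, n_orthogonal, folds, seed,
                       scale = FALSE) {
  X <- as.matrix(X)
  Y <- dummy_response(labels)
  fold_id <- stratified_folds(labels, folds, seed)
  A <- n_predictive
  press <- numeric(A)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    core <- opls_core(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                      A, n_orthogonal, scale = scale)
    Xc <- sweep(sweep(X[te, , drop = FALSE], 2, core$x_mean), 2,
                core$x_scale, "/")
    Tm <- opls_scores_seq(core, opls_filter(core, Xc))
    Yte_c <- sweep(Y[te, , drop = FALSE], 2, core$y_mean)
    for (a in seq_len(A)) {
      Yhat <- Tm[, seq_len(a), drop = FALSE] %*%
        t(core$y_loadings[, seq_len(a), drop = FALSE])
      press[a] <- press[a] + sum((Yte_c - Yhat)^2)
    }
  }
  full <- opls_core(X, Y, A, n_orthogonal, scale = scale)
  ss_prev <- full$ssy_path[seq_len(A)]  # SS after 0..A-1 components
  q2_per <- 1 - press / ss_prev
  list(q2_cum = 1 - prod(press / ss_prev), q2_per_component = q2_per,
       press = press)
}

#' Predict class membership from an OPLS-DA model
#'
#' Applies the stored centering/scaling, removes orthogonal variation with
#' the stored orthogonal weights, projects onto the predictive components
#' and reconstructs the dummy-response estimates. The predicted label is
#' the class with the maximum estimated response; exact ties are broken in
#' class order with a warning.
#'
#' @param model an `opls_model`.
#' @param x_new matrix (or [spectrum_set()]) with the training variable
#'   count.
#' @return list with `scores` (continuous per-class response estimates),
#'   `labels` (factor of predicted classes) and `t` (predictive score
#'   matrix).
#' @export
predict_opls <- function(model, x_new) {
  if (inherits(x_new, "spectrum_set")) x_new <- x_new$intensities
  x_new <- if (is.null(dim(x_new))) matrix(x_new, nrow = 1) else as.matrix(x_new)
  if (ncol(x_new) != length(model$x_mean)) {
    stop(sprintf("x_new has %d variables; model was trained on %d",
                 ncol(x_new), length(model$x_mean)))
  }
  Xc <- sweep(sweep(x_new, 2, model$x_mean), 2, model$x_scale, "/")
  Tm <- opls_scores_seq(model, opls_filter(model, Xc))
  Yhat <- sweep(Tm %*% t(model$y_loadings), 2, model$y_mean, "+")
  colnames(Yhat) <- model$class_labels
  idx <- apply(Yhat, 1, function(r) {
    top <- which(r == max(r))
    if (length(top) > 1) warning("tie in class scores; first class taken")
    top[1]
  })
  list(scores = Yhat,
       labels = factor(model$class_labels[idx], levels = model$class_labels),
       t = Tm)
}

#' Score table for a 2-D model plot
#'
#' Exports the first predictive score against the second predictive score
#' (or the first orthogonal score when only one predictive component
#' exists), with class labels and the parameters of the 95% Hotelling T2
#' confidence ellipse.
#'
#' @param model a fitted `opls_model` with at least 2 total components.
#' @param level confidence level of the ellipse.
#' @return list with `scores` (data.frame: sample, t1, t2, label) and
#'   `ellipse` (centre, semi-axes, the scores' standard deviations and the
#'   F-quantile scale factor).
#' @export
scores_for_plot <- function(model, level = 0.95) {
  t1 <- model$scores[, 1]
  if (model$n_predictive >= 2) {
    t2 <- model$scores[, 2]
    t2_name <- "predictive_2"
  } else if (model$n_orthogonal >= 1) {
    t2 <- model$ortho_scores[, 1]
    t2_name <- "orthogonal_1"
  } else {
    stop("at least 2 components (predictive + orthogonal) are required")
  }
  n <- length(t1)
  # Hotelling T2 ellipse for 2 uncorrelated score columns
  f_scale <- 2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2)
  ellipse <- list(center = c(0, 0),
                  sd = c(stats::sd(t1), stats::sd(t2)),
                  semi_axes = sqrt(f_scale) * c(stats::sd(t1), stats::sd(t2)),
                  f_scale = f_scale, level = level)
  scores <- data.frame(sample = rownames(model$scores) %||%
                         seq_along(t1),
                       t1 = t1, t2 = t2,
                       label = model$labels,
                       stringsAsFactors = FALSE)
  attr(scores, "t2_axis") <- t2_name
  list(scores = scores, ellipse = ellipse)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "opls_model: %d predictive + %d orthogonal component(s), %d classes\n",
    x$n_predictive, x$n_orthogonal, length(x$class_labels)))
  cat(sprintf("R2X(cum) = %.3f  R2Y(cum) = %.3f  Q2(cum) = %.3f (%d-fold CV)\n",
              x$r2x_cum, x$r2y_cum, x$q2_cum, x$cv_folds))
  invisible(x)
}
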