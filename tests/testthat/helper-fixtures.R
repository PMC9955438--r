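# Shared fixtures: all synthetic, generated in code.

# Small fast cohort (same structure as the default, fewer samples).
small_cohort <- function(seed = 1, effect_scale = 1, ...) {
  generate_cohort(cohort_config(
    class_sizes = c(healthy = 18, stone = 14, polyp = 10),
    bands = default_serum_bands(effect_scale = effect_scale),
    seed = seed, ...))
}

# Two well-separated Gaussian point clouds in `p` dimensions.
two_clouds <- function(n_per = 10, p = 5, sep = 8, seed = 1, sd = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p, 0, sd), n_per),
             matrix(rnorm(n_per * p, 0, sd), n_per))
  X[(n_per + 1):(2 * n_per), 1] <- X[(n_per + 1):(2 * n_per), 1] + sep
  list(X = X, labels = factor(rep(c("a", "b"), each = n_per)))
}

# Independent single-component PLS2 fit for binary dummy response.
# For a 2-class dummy Y the NIPALS weight is proportional to t(X) %*% y1
# (centered), so the component has a closed form.
oracle_pls1_binary <- function(X, labels) {
  Y <- cbind(as.numeric(labels == levels(labels)[1]),
             as.numeric(labels == levels(labels)[2]))
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
  w <- drop(crossprod(Xc, Yc[, 1]))
  w <- w / sqrt(sum(w^2))
  tt <- drop(Xc %*% w)
  cc <- drop(crossprod(Yc, tt)) / sum(tt^2)
  list(x_mean = x_mean, y_mean = y_mean, w = w, t = tt, c = cc,
       p = drop(crossprod(Xc, tt)) / sum(tt^2))
}

# Brute-force fold-refit PRESS/Q2 oracle for a 1-component binary model.
oracle_q2_folds <- function(X, labels, fold_id) {
  Y <- cbind(as.numeric(labels == levels(labels)[1]),
             as.numeric(labels == levels(labels)[2]))
  press <- 0
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    fit <- oracle_pls1_binary(X[tr, , drop = FALSE], droplevels(labels[tr]))
    Xc <- sweep(X[!tr, , drop = FALSE], 2, fit$x_mean)
    t_new <- drop(Xc %*% fit$w)
    Yhat <- outer(t_new, fit$c)
    Yc <- sweep(Y[!tr, , drop = FALSE], 2, fit$y_mean)
    press <- press + sum((Yc - Yhat)^2)
  }
  ss0 <- sum(sweep(Y, 2, colMeans(Y))^2)
  1 - press / ss0
}

# Brute-force local polynomial fit: the Savitzky-Golay definition.
oracle_sg <- function(x, window, polyorder) {
  n <- length(x); h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    win <- if (i <= h) 1:window else if (i > n - h) (n - window + 1):n else
      (i - h):(i + h)
    V <- outer(win, 0:polyorder, "^")
    beta <- qr.solve(V, x[win])
    out[i] <- sum(beta * i^(0:polyorder))
  }
  out
}

# Dense-matrix Whittaker smoother solve (independent of Matrix sparse path).
oracle_whittaker <- function(x, w, lambda) {
  m <- length(x)
  D <- diff(diag(m), differences = 2)
  solve(diag(w) + lambda * t(D) %*% D, w * x)
}

# Textbook one-way ANOVA F from between/within mean squares.
oracle_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  k <- nlevels(groups); n <- length(values)
  ss_between <- sum(tapply(values, groups, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  ss_within <- sum(tapply(values, groups, function(v) {
    sum((v - mean(v))^2)
  }))
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(f = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Pair-counting AUC: concordant pairs + half ties.
oracle_auc_pairs <- function(scores, membership) {
  pos <- scores[membership]; neg <- scores[!membership]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Shared-covariance Gaussian Bayes rule with equal priors.
oracle_bayes_lda <- function(X, labels, X_new) {
  labels <- as.factor(labels)
  mus <- lapply(levels(labels), function(cl) {
    colMeans(X[labels == cl, , drop = FALSE])
  })
  pooled <- Reduce(`+`, lapply(levels(labels), function(cl) {
    Xi <- X[labels == cl, , drop = FALSE]
    crossprod(sweep(Xi, 2, colMeans(Xi)))
  })) / (nrow(X) - nlevels(labels))
  Sinv <- solve(pooled)
  d2 <- sapply(mus, function(mu) {
    apply(X_new, 1, function(x) drop(t(x - mu) %*% Sinv %*% (x - mu)))
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  factor(levels(labels)[apply(d2, 1, which.min)], levels = levels(labels))
}
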