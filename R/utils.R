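# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounding convention used for all percent metrics reported at one decimal
#' place, so that e.g. 92.65 -> 92.7 rather than banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `folds` cross-validation folds so that every
#' class is spread as evenly as possible across folds. Reproducible for a
#' fixed seed; the seed is restored-free (uses a local RNG stream).
#'
#' @param labels factor of class labels.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..folds, one per sample.
#' @keywords internal
stratified_folds <- function(labels, folds, seed) {
  labels <- as.factor(labels)
  if (folds < 2) stop("'folds' must be at least 2")
  smallest <- min(table(labels))
  if (folds > smallest) {
    stop(sprintf("folds (%d) exceeds the smallest class size (%d)", folds, smallest))
  }
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  eval.parent(substitute(expr))
}

# Percent with one-decimal half-up rounding.
pct1 <- function(x) round_half_up(100 * x, 1)
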