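#' Preprocessing configuration
#'
#' Parameters of the three-stage chain applied to raw serum SERS spectra:
#' Savitzky-Golay smoothing, airPLS baseline removal and vector
#' normalization. The smoothing default is a 9-point window with a
#' degree-5 polynomial; airPLS defaults to lambda = 1e4 with at most 15
#' reweighting iterations and a 0.1% negative-residual stopping fraction.
#'
#' @param sg_window odd number of points in the smoothing window.
#' @param sg_polyorder polynomial degree, strictly below `sg_window`.
#' @param airpls_lambda positive second-difference smoothness penalty.
#' @param airpls_max_iter maximum reweighting iterations (>= 1).
#' @param airpls_tol stopping fraction in (0, 1): iteration ends when the
#'   summed magnitude of negative residuals falls below `tol` times the
#'   total absolute intensity.
#' @param normalize whether to vector-normalize each spectrum at the end.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 9, sg_polyorder = 5,
                              airpls_lambda = 1e4, airpls_max_iter = 15,
                              airpls_tol = 0.001, normalize = TRUE) {
  if (sg_window %% 2 == 0) stop("sg_window must be odd")
  if (sg_polyorder >= sg_window) stop("sg_polyorder must be below sg_window")
  if (airpls_lambda <= 0) stop("airpls_lambda must be positive")
  if (airpls_max_iter < 1) stop("airpls_max_iter must be >= 1")
  if (airpls_tol <= 0 || airpls_tol >= 1) stop("airpls_tol must be in (0, 1)")
  structure(
    list(sg_window = sg_window, sg_polyorder = sg_polyorder,
         airpls_lambda = airpls_lambda, airpls_max_iter = airpls_max_iter,
         airpls_tol = airpls_tol, normalize = normalize),
    class = "preprocess_config"
  )
}

#' Savitzky-Golay smoothing
#'
#' Replaces each spectrum by its local least-squares polynomial filtering;
#' the terminal windows are handled by the polynomial fit within the first
#' and last window (no padding artefacts). Reproduces any polynomial of
#' degree at most `polyorder` exactly, and is linear in the input.
#'
#' @param set a [spectrum_set()].
#' @param window odd window length in points.
#' @param polyorder polynomial degree (< window).
#' @return a smoothed `spectrum_set`.
#' @export
savitzky_golay_smooth <- function(set, window = 9, polyorder = 5) {
  if (window %% 2 == 0) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be below the window length")
  p <- length(set$wavenumbers)
  if (window >= p) stop("window must be shorter than the spectrum")
  sm <- t(apply(set$intensities, 1, function(x) {
    signal::sgolayfilt(x, p = polyorder, n = window)
  }))
  set_intensities(set, sm)
}

# Whittaker smoother solve: minimises sum(w*(x-z)^2) + lambda*sum(diff(z,2)^2).
whittaker_solve <- function(x, w, lambda) {
  m <- length(x)
  D <- Matrix::bandSparse(m - 2, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2),
                                           rep(-2, m - 2),
                                           rep(1, m - 2)))
  A <- Matrix::Diagonal(m, w) + lambda * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, w * x))
}

#' airPLS baseline estimation
#'
#' Adaptive iteratively reweighted penalized least squares: the baseline
#' is a Whittaker smoother (second-difference penalty `lambda`) fitted
#' under weights that are re-estimated every iteration — zero wherever the
#' spectrum rises above the current baseline (peaks), and exponentially
#' increasing with the magnitude of negative residuals elsewhere, so the
#' baseline is pulled onto the peak-free parts of the spectrum.
#' Iteration stops after `max_iter` rounds or when the summed magnitude of
#' negative residuals drops below `tol` times the total absolute
#' intensity.
#'
#' @param spectrum finite numeric vector (length >= 4).
#' @param lambda positive smoothness penalty; larger gives a stiffer
#'   baseline.
#' @param max_iter maximum reweighting iterations.
#' @param tol relative stopping fraction in (0, 1).
#' @return list with `baseline` and `corrected` (= spectrum - baseline).
#' @export
airpls_baseline <- function(spectrum, lambda = 1e4, max_iter = 15,
                            tol = 0.001) {
  if (any(!is.finite(spectrum))) stop("spectrum must be finite")
  if (lambda <= 0) stop("lambda must be positive")
  m <- length(spectrum)
  if (m < 4) stop("spectrum must have at least 4 points")
  w <- rep(1, m)
  z <- spectrum
  total <- sum(abs(spectrum))
  for (it in seq_len(max_iter)) {
    z <- whittaker_solve(spectrum, w, lambda)
    d <- spectrum - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    if (dssn < tol * total || total == 0) break
    w[!neg] <- 0
    w[neg] <- exp(it * abs(d[neg]) / dssn)
    # keep the ends anchored so the baseline cannot drift free there
    w[1] <- exp(it * max(d[neg]) / dssn)
    w[m] <- w[1]
  }
  list(baseline = z, corrected = spectrum - z)
}

#' Vector normalization
#'
#' Divides each spectrum by its Euclidean norm so every row of the output
#' has unit length; removes overall intensity variation between samples.
#' Scale-invariant and idempotent.
#'
#' @param set a [spectrum_set()].
#' @return a `spectrum_set` with unit-norm rows.
#' @export
vector_normalize <- function(set) {
  norms <- sqrt(rowSums(set$intensities^2))
  zero <- norms == 0
  if (any(zero)) {
    stop(sprintf("cannot normalize all-zero spectrum: '%s'",
                 set$sample_ids[which(zero)[1]]))
  }
  set_intensities(set, set$intensities / norms)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: Savitzky-Golay smoothing, per-spectrum airPLS
#' baseline correction, and (optionally) vector normalization. The stage
#' order and parameters are recorded in the result's `trace` attribute.
#'
#' @param set a [spectrum_set()] of raw spectra.
#' @param config a [preprocess_config()].
#' @return the preprocessed `spectrum_set`; `attr(, "trace")` lists the
#'   stages applied with their parameters.
#' @export
preprocess_pipeline <- function(set, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  trace <- list()
  out <- savitzky_golay_smooth(set, config$sg_window, config$sg_polyorder)
  trace$smooth <- list(stage = "savitzky_golay",
                       window = config$sg_window,
                       polyorder = config$sg_polyorder)
  corrected <- t(apply(out$intensities, 1, function(x) {
    airpls_baseline(x, config$airpls_lambda, config$airpls_max_iter,
                    config$airpls_tol)$corrected
  }))
  out <- set_intensities(out, corrected)
  trace$baseline <- list(stage = "airpls", lambda = config$airpls_lambda,
                         max_iter = config$airpls_max_iter,
                         tol = config$airpls_tol)
  if (isTRUE(config$normalize)) {
    out <- vector_normalize(out)
    trace$normalize <- list(stage = "vector_normalize")
  }
  attr(out, "trace") <- trace
  out
}
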