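#' Describe one Raman band
#'
#' A band is modelled as a Lorentzian line (the typical Raman lineshape)
#' with a fixed centre and full width at half maximum, a base peak
#' amplitude, and one positive multiplier per class that scales the
#' amplitude for samples of that class.
#'
#' @param center band centre (cm^-1).
#' @param width full width at half maximum (cm^-1); must be positive.
#' @param base_amplitude peak height in arbitrary intensity units (>= 0).
#' @param class_multipliers named numeric vector, one positive factor per
#'   class label.
#' @param assignment free-text biochemical assignment (optional).
#' @return an object of class `band_spec`.
#' @export
band_spec <- function(center, width = 16, base_amplitude = 1,
                      class_multipliers = c(healthy = 1),
                      assignment = NA_character_) {
  stopifnot(width > 0, base_amplitude >= 0)
  if (is.null(names(class_multipliers)) || any(names(class_multipliers) == "")) {
    stop("class_multipliers must be a named vector")
  }
  if (any(class_multipliers <= 0)) stop("class multipliers must be positive")
  structure(
    list(center = center, width = width, base_amplitude = base_amplitude,
         class_multipliers = class_multipliers, assignment = assignment),
    class = "band_spec"
  )
}

#' Default serum SERS band set
#'
#' The 11 characteristic serum bands at 637, 722, 810, 888, 1003, 1134,
#' 1203, 1333, 1432, 1557 and 1652 cm^-1 with their biochemical
#' assignments, and default class multipliers encoding the qualitative
#' group differences reported for benign gallbladder disease: the stone
#' class is depressed at 888 cm^-1 (glutathione) relative to healthy, the
#' polyp class is elevated at 1203 cm^-1 (phenylalanine), stone and polyp
#' differ at 637, 722, 1203, 1432 and 1652 cm^-1, polyp additionally
#' differs from healthy at 1134 cm^-1, and 810, 1003, 1333 and 1557 cm^-1
#' carry no class effect. Multipliers are chosen so each class's total
#' band intensity stays approximately balanced, which keeps
#' vector-normalized null bands close to null.
#'
#' @param effect_scale scales the log-multipliers: 0 removes all class
#'   effects, 1 is the default effect size, larger values increase
#'   separation (used to configure statistical power in simulations).
#' @return list of [band_spec()] objects, centres ascending.
#' @export
default_serum_bands <- function(effect_scale = 1) {
  tab <- list(
    #       center amp  stone polyp assignment
    list(637,  0.90, 1.25, 0.65, "L-tyrosine, lactose"),
    list(722,  0.70, 1.20, 1.30, "Coenzyme A"),
    list(810,  0.50, 1.00, 1.00, "L-serine, glutathione"),
    list(888,  0.80, 0.68, 1.00, "Tryptophan, glutathione"),
    list(1003, 1.00, 1.00, 1.00, "Phenylalanine"),
    list(1134, 0.60, 1.00, 1.25, "D-mannose"),
    list(1203, 0.70, 1.16, 1.25, "L-tryptophan, phenylalanine"),
    list(1333, 0.80, 1.00, 1.00, "Guanine, adenine"),
    list(1432, 0.60, 1.00, 1.25, "D-glucosamine"),
    list(1557, 0.50, 1.00, 1.00, "Tryptophan"),
    list(1652, 0.90, 0.75, 0.60, "Lipids")
  )
  lapply(tab, function(b) {
    mult <- c(healthy = 1, stone = b[[3]], polyp = b[[4]])
    band_spec(
      center = b[[1]], width = 16, base_amplitude = b[[2]],
      class_multipliers = exp(effect_scale * log(mult)),
      assignment = b[[5]]
    )
  })
}

#' Configure a synthetic serum-SERS cohort
#'
#' Defaults emulate the study cohort the analysis is designed for: 72
#' healthy controls, 51 gallbladder-stone and 25 gallbladder-polyp
#' patients, spectra on a 600-1800 cm^-1 grid (2 cm^-1 step), the 11-band
#' serum signature, a broad autofluorescence background (one wide Gaussian
#' hump plus a linear tilt) whose amplitude varies per sample, additive
#' Gaussian instrument noise, and 5 technical replicates per sample that
#' are averaged into the sample's spectrum.
#'
#' @param class_sizes named integer vector of samples per class.
#' @param grid_start,grid_stop,grid_step wavenumber grid (cm^-1).
#' @param bands list of [band_spec()].
#' @param baseline_params list with `amplitude` (hump height), `center`
#'   and `fwhm` (cm^-1) of the Gaussian hump, and `slope` (intensity per
#'   cm^-1 linear tilt).
#' @param noise_sd additive Gaussian noise SD per replicate point.
#' @param replicates_per_sample technical replicates averaged per sample.
#' @param band_jitter_sd SD of the per-sample, per-band lognormal
#'   amplitude jitter (on the log scale); creates within-class spread.
#' @param baseline_jitter_sd SD of the per-sample lognormal jitter applied
#'   to the baseline amplitude and slope.
#' @param seed integer RNG seed; the cohort is fully reproducible from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(class_sizes = c(healthy = 72, stone = 51, polyp = 25),
                          grid_start = 600, grid_stop = 1800, grid_step = 2,
                          bands = default_serum_bands(),
                          baseline_params = list(amplitude = 2, center = 1300,
                                                 fwhm = 600, slope = 2.5e-4),
                          noise_sd = 0.03,
                          replicates_per_sample = 5,
                          band_jitter_sd = 0.15,
                          baseline_jitter_sd = 0.2,
                          seed = 1) {
  if (is.null(names(class_sizes))) stop("class_sizes must be named")
  if (any(class_sizes <= 0)) stop("class sizes must be positive")
  if (grid_start >= grid_stop) stop("grid_start must be below grid_stop")
  if (replicates_per_sample < 1) stop("replicates_per_sample must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(
    list(class_sizes = class_sizes, grid_start = grid_start,
         grid_stop = grid_stop, grid_step = grid_step, bands = bands,
         baseline_params = baseline_params, noise_sd = noise_sd,
         replicates_per_sample = replicates_per_sample,
         band_jitter_sd = band_jitter_sd,
         baseline_jitter_sd = baseline_jitter_sd, seed = seed),
    class = "cohort_config"
  )
}

# Lorentzian profile with unit peak height.
lorentzian <- function(x, center, fwhm) {
  hw2 <- (fwhm / 2)^2
  hw2 / ((x - center)^2 + hw2)
}

#' Generate a synthetic serum-SERS cohort
#'
#' Each raw replicate spectrum is the sum of Lorentzian bands (amplitude =
#' base amplitude x class multiplier x per-sample lognormal jitter), a
#' broad per-sample fluorescence baseline and additive Gaussian noise;
#' replicates are averaged into one spectrum per sample, mirroring the
#' measure-five-times-and-average acquisition convention. Deterministic
#' for a fixed `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `spectra` (a [spectrum_set()] of replicate-averaged
#'   raw spectra) and `truth` (ground-truth record: per-sample labels,
#'   the band-by-class multiplier matrix, per-sample baseline draws and
#'   band centres).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  wn <- seq(config$grid_start, config$grid_stop, by = config$grid_step)
  for (b in config$bands) {
    if (b$center < min(wn) || b$center > max(wn)) {
      stop(sprintf("band at %.1f cm^-1 lies outside the grid span %.0f-%.0f",
                   b$center, min(wn), max(wn)))
    }
  }
  classes <- names(config$class_sizes)
  labels <- factor(rep(classes, times = config$class_sizes), levels = classes)
  n <- length(labels)
  p <- length(wn)
  nb <- length(config$bands)

  mult <- vapply(config$bands, function(b) {
    miss <- setdiff(classes, names(b$class_multipliers))
    if (length(miss)) {
      stop(sprintf("band at %.0f cm^-1 lacks multipliers for class(es): %s",
                   b$center, paste(miss, collapse = ", ")))
    }
    b$class_multipliers[classes]
  }, numeric(length(classes)))
  mult <- matrix(mult, nrow = length(classes),
                 dimnames = list(classes,
                                 vapply(config$bands, `[[`, 0, "center")))

  # Precompute unit-height band profiles (p x nb).
  profiles <- vapply(config$bands,
                     function(b) lorentzian(wn, b$center, b$width),
                     numeric(p))
  base_amp <- vapply(config$bands, `[[`, 0, "base_amplitude")

  bp <- config$baseline_params
  hump_sd <- bp$fwhm / (2 * sqrt(2 * log(2)))
  hump <- exp(-(wn - bp$center)^2 / (2 * hump_sd^2))
  tilt <- wn - config$grid_start

  intens <- matrix(0, n, p)
  base_draws <- data.frame(sample = seq_len(n),
                           hump_amplitude = numeric(n), slope = numeric(n))
  with_seed(config$seed, {
    for (i in seq_len(n)) {
      cls <- as.character(labels[i])
      jitter <- exp(stats::rnorm(nb, 0, config$band_jitter_sd))
      amps <- base_amp * mult[cls, ] * jitter
      signal_i <- drop(profiles %*% amps)
      amp_s <- bp$amplitude * exp(stats::rnorm(1, 0, config$baseline_jitter_sd))
      slope_s <- bp$slope * exp(stats::rnorm(1, 0, config$baseline_jitter_sd))
      base_draws$hump_amplitude[i] <- amp_s
      base_draws$slope[i] <- slope_s
      baseline_i <- amp_s * hump + slope_s * tilt
      acc <- numeric(p)
      for (r in seq_len(config$replicates_per_sample)) {
        noise <- if (config$noise_sd > 0) {
          stats::rnorm(p, 0, config$noise_sd)
        } else numeric(p)
        acc <- acc + signal_i + baseline_i + noise
      }
      intens[i, ] <- acc / config$replicates_per_sample
    }
  })

  ids <- sprintf("%s_%03d", labels, stats::ave(seq_len(n), labels,
                                               FUN = seq_along))
  spectra <- spectrum_set(wn, intens, labels, ids)
  truth <- list(
    labels = labels,
    multipliers = mult,
    band_centers = as.numeric(colnames(mult)),
    baseline_draws = base_draws,
    config = config
  )
  list(spectra = spectra, truth = truth)
}

#' Write ground truth to JSON
#'
#' @param truth the `truth` element returned by [generate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    labels = as.character(truth$labels),
    band_centers = truth$band_centers,
    multipliers = as.data.frame(truth$multipliers),
    baseline_draws = truth$baseline_draws
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
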