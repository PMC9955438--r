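#' Class mean and difference spectra
#'
#' Pointwise class means and standard deviations plus the difference
#' spectrum `mean(a) - mean(b)`, the standard display for comparing two
#' patient groups' average SERS profiles.
#'
#' @param set a [spectrum_set()].
#' @param class_a,class_b class labels to compare.
#' @return data.frame with wavenumber, mean_a, sd_a, mean_b, sd_b and
#'   difference columns.
#' @export
mean_and_difference_spectra <- function(set, class_a, class_b) {
  for (cl in c(class_a, class_b)) {
    if (!any(set$labels == cl)) stop(sprintf("class '%s' has no samples", cl))
  }
  ma <- set$intensities[set$labels == class_a, , drop = FALSE]
  mb <- set$intensities[set$labels == class_b, , drop = FALSE]
  sd0 <- function(m) if (nrow(m) > 1) apply(m, 2, stats::sd) else
    rep(0, ncol(m))
  out <- data.frame(
    wavenumber = set$wavenumbers,
    mean_a = colMeans(ma), sd_a = sd0(ma),
    mean_b = colMeans(mb), sd_b = sd0(mb)
  )
  out$difference <- out$mean_a - out$mean_b
  attr(out, "classes") <- c(a = class_a, b = class_b)
  out
}

#' Extract per-sample peak intensity
#'
#' For each sample, the maximum intensity within `half_width` cm^-1 of
#' the nominal peak position (robust to small peak shifts); the grid
#' position of the located maximum is recorded. A half-width of 0
#' degenerates to the intensity at the nearest grid point.
#'
#' @param set a [spectrum_set()].
#' @param wavenumber nominal peak position (cm^-1), inside the grid.
#' @param half_width search half-width (cm^-1, default 8).
#' @return data.frame with sample_id, label, intensity and the located
#'   wavenumber per sample.
#' @export
extract_peak_intensity <- function(set, wavenumber, half_width = 8) {
  wn <- set$wavenumbers
  if (wavenumber < min(wn) || wavenumber > max(wn)) {
    stop(sprintf("peak position %.1f cm^-1 lies outside the grid", wavenumber))
  }
  if (half_width == 0) {
    idx <- which.min(abs(wn - wavenumber))
  } else {
    idx <- which(wn >= wavenumber - half_width & wn <= wavenumber + half_width)
    if (!length(idx)) stop("search window contains no grid points")
  }
  sub <- set$intensities[, idx, drop = FALSE]
  at <- apply(sub, 1, which.max)
  data.frame(
    sample_id = set$sample_ids,
    label = set$labels,
    intensity = sub[cbind(seq_len(nrow(sub)), at)],
    located_wavenumber = wn[idx][at],
    stringsAsFactors = FALSE
  )
}

#' Peak-level one-way ANOVA table
#'
#' Extracts each peak's per-sample intensity ([extract_peak_intensity()])
#' and compares the class groups with fixed-effects one-way ANOVA. No
#' multiple-testing correction is applied to the `significant` flag
#' (matching common practice for small fixed peak panels); a Bonferroni
#' column is emitted alongside for transparency.
#'
#' @param set a [spectrum_set()].
#' @param peaks numeric vector of nominal peak positions, or a list of
#'   [band_spec()] (whose assignments are carried through); defaults to
#'   [default_serum_bands()].
#' @param alpha significance cut-off (default 0.05).
#' @param half_width search half-width passed to
#'   [extract_peak_intensity()].
#' @return data.frame (`peak_table`): wavenumber, assignment, per-class
#'   mean and sd columns, F, p, significant, p_bonferroni.
#' @export
anova_peaks <- function(set, peaks = default_serum_bands(), alpha = 0.05,
                        half_width = 8) {
  if (nlevels(set$labels) < 2) stop("at least 2 classes are required")
  if (min(table(set$labels)) < 2) {
    stop("every class needs at least 2 samples for ANOVA")
  }
  if (is.list(peaks)) {
    centers <- vapply(peaks, `[[`, 0, "center")
    assignments <- vapply(peaks, function(b) {
      as.character(b$assignment %||% NA_character_)
    }, "")
  } else {
    centers <- as.numeric(peaks)
    assignments <- rep(NA_character_, length(centers))
  }
  classes <- levels(set$labels)
  rows <- lapply(seq_along(centers), function(i) {
    pk <- extract_peak_intensity(set, centers[i], half_width)
    test <- stats::oneway.test(intensity ~ label, data = pk,
                               var.equal = TRUE)
    stat <- unname(test$statistic)
    pval <- unname(test$p.value)
    if (is.nan(stat)) { stat <- 0; pval <- 1 }  # zero between-group spread
    means <- tapply(pk$intensity, pk$label, mean)
    sds <- tapply(pk$intensity, pk$label, stats::sd)
    out <- data.frame(wavenumber = centers[i], assignment = assignments[i],
                      F = stat, p = pval, stringsAsFactors = FALSE)
    for (cl in classes) {
      out[[paste0("mean_", cl)]] <- means[[cl]]
      out[[paste0("sd_", cl)]] <- sds[[cl]]
    }
    out
  })
  tab <- do.call(rbind, rows)
  tab$significant <- tab$p < alpha
  tab$p_bonferroni <- pmin(1, tab$p * nrow(tab))
  attr(tab, "alpha") <- alpha
  class(tab) <- c("peak_table", "data.frame")
  tab
}
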