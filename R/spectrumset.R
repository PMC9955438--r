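#' Construct a SpectrumSet
#'
#' A `spectrum_set` is the package's container for a cohort of spectra on a
#' shared wavenumber grid: an `n x p` intensity matrix, the ascending
#' wavenumber axis (cm^-1), one class label per sample and unique sample ids.
#'
#' @param wavenumbers strictly increasing numeric vector (cm^-1).
#' @param intensities numeric matrix, samples in rows, one column per
#'   wavenumber. No missing values.
#' @param labels class label per sample (character or factor).
#' @param sample_ids unique sample identifiers; defaults to `sample_1..n`.
#' @return an object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavenumbers, intensities, labels,
                         sample_ids = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.matrix(intensities)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample_", seq_len(nrow(intensities)))
  }
  sample_ids <- as.character(sample_ids)
  labels <- if (is.factor(labels)) labels else factor(labels)

  if (any(!is.finite(wavenumbers))) stop("wavenumbers must be finite")
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be strictly increasing")
  }
  if (ncol(intensities) != length(wavenumbers)) {
    stop("intensity column count must equal wavenumber count")
  }
  if (nrow(intensities) != length(labels)) {
    stop("one label per sample is required")
  }
  if (nrow(intensities) != length(sample_ids)) {
    stop("one sample id per sample is required")
  }
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1]
    stop(sprintf("duplicate sample_id: '%s'", dup))
  }
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite (no missing values)")
  }
  rownames(intensities) <- sample_ids
  structure(
    list(
      wavenumbers = wavenumbers,
      intensities = intensities,
      labels = droplevels(labels),
      sample_ids = sample_ids
    ),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf(
    "spectrum_set: %d spectra x %d wavenumbers (%.0f-%.0f cm^-1)\n",
    nrow(x$intensities), length(x$wavenumbers),
    min(x$wavenumbers), max(x$wavenumbers)
  ))
  tab <- table(x$labels)
  cat("classes:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$intensities)

# Replace the intensity matrix, keeping axis/labels/ids.
set_intensities <- function(set, m) {
  spectrum_set(set$wavenumbers, m, set$labels, set$sample_ids)
}

#' Subset a SpectrumSet by sample
#'
#' @param set a `spectrum_set`.
#' @param i integer or logical index over samples.
#' @return a `spectrum_set` with the selected samples.
#' @export
subset_samples <- function(set, i) {
  spectrum_set(set$wavenumbers, set$intensities[i, , drop = FALSE],
               set$labels[i], set$sample_ids[i])
}

#' Read a SpectrumSet from wide CSV
#'
#' Expects a header `sample_id,label,<wn_1>,...,<wn_p>` where the wavenumber
#' headers are numeric and strictly increasing, followed by one row per
#' sample. Duplicate sample ids and non-numeric intensity cells are rejected
#' with the offending line reported.
#'
#' @param path CSV file path.
#' @return a `spectrum_set`.
#' @seealso [write_spectrumset()]
#' @export
read_spectrumset <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 3 || !identical(names(raw)[1:2], c("sample_id", "label"))) {
    stop("expected header 'sample_id,label,<wavenumber>,...'")
  }
  wn <- suppressWarnings(as.numeric(names(raw)[-(1:2)]))
  if (any(is.na(wn))) stop("wavenumber column headers must be numeric")
  if (any(diff(wn) <= 0)) stop("wavenumber headers must be strictly increasing")
  ids <- raw$sample_id
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop(sprintf("duplicate sample_id '%s' (line %d)",
                 dup, which(ids == dup)[2] + 1L))
  }
  m <- matrix(NA_real_, nrow(raw), length(wn))
  for (j in seq_along(wn)) {
    v <- suppressWarnings(as.numeric(raw[[j + 2L]]))
    if (any(is.na(v))) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric intensity at line %d, column '%s'",
                   bad + 1L, names(raw)[j + 2L]))
    }
    m[, j] <- v
  }
  spectrum_set(wn, m, raw$label, ids)
}

#' Write a SpectrumSet to wide CSV
#'
#' Values are serialized with 17 significant digits so a write/read
#' round-trip reproduces the matrix bit-exactly.
#'
#' @param set a `spectrum_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrumset <- function(set, path) {
  num <- apply(set$intensities, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  out <- cbind(sample_id = set$sample_ids,
               label = as.character(set$labels), num)
  colnames(out) <- c("sample_id", "label",
                     sprintf("%.10g", set$wavenumbers))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
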