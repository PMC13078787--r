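#' Container for single-cell spectra with condition metadata
#'
#' @param intensities cells x channels numeric matrix.
#' @param wavenumbers strictly increasing channel axis in cm^-1.
#' @param condition per-cell condition label.
#' @param replicate per-cell replicate label.
#' @param cell_id optional per-cell id; generated if missing.
#' @return list of class `spectra_set`.
#' @export
spectra_set <- function(intensities, wavenumbers, condition, replicate,
                        cell_id = NULL) {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(wavenumbers)) {
    stop("wavenumber axis does not match the number of channels",
         call. = FALSE)
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("intensity matrix contains non-finite values", call. = FALSE)
  }
  n <- nrow(intensities)
  if (length(condition) != n || length(replicate) != n) {
    stop("label arrays must match the cell count", call. = FALSE)
  }
  if (is.null(cell_id)) cell_id <- sprintf("cell%04d", seq_len(n))
  structure(list(intensities = intensities,
                 wavenumbers = as.numeric(wavenumbers),
                 condition = as.character(condition),
                 replicate = replicate,
                 cell_id = cell_id),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d cells x %d channels (%.1f-%.1f cm^-1), %d conditions\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$wavenumbers), max(x$wavenumbers),
              length(unique(x$condition))))
  invisible(x)
}

#' Subtract a background spectrum
#'
#' Element-wise subtraction of a background from a cellular spectrum or
#' from every cell of a [spectra_set()]. Channel counts (and wavenumber
#' axes, when both carry one) must match.
#'
#' @param x numeric spectrum or `spectra_set`.
#' @param background numeric background spectrum of the same length.
#' @return object of the same shape as `x`.
#' @export
subtract_background <- function(x, background) {
  if (inherits(x, "spectra_set")) {
    if (length(background) != ncol(x$intensities)) {
      stop("background axis does not match the spectra", call. = FALSE)
    }
    x$intensities <- sweep(x$intensities, 2, as.numeric(background), "-")
    return(x)
  }
  if (length(x) != length(background)) {
    stop("background axis does not match the spectrum", call. = FALSE)
  }
  x - background
}

#' Crop spectra to a closed wavenumber interval
#'
#' Retains channels with `lo <= w <= hi` (ties included), preserving axis
#' order.
#'
#' @param spectra a [spectra_set()].
#' @param lo,hi interval bounds in cm^-1, `lo < hi`.
#' @return cropped `spectra_set`.
#' @export
crop_spectra <- function(spectra, lo, hi) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (lo >= hi) stop("'lo' must be smaller than 'hi'", call. = FALSE)
  keep <- spectra$wavenumbers >= lo & spectra$wavenumbers <= hi
  if (!any(keep)) {
    stop("crop interval does not overlap the wavenumber axis", call. = FALSE)
  }
  spectra$intensities <- spectra$intensities[, keep, drop = FALSE]
  spectra$wavenumbers <- spectra$wavenumbers[keep]
  spectra
}

#' Savitzky-Golay smoothing of spectra
#'
#' Local least-squares polynomial smoothing, applied per spectrum. Interior
#' values of an exact polynomial of degree <= `polyorder` are reproduced
#' exactly.
#'
#' @param spectra a [spectra_set()].
#' @param window odd filter length, `polyorder < window <= channel count`.
#' @param polyorder polynomial order.
#' @return smoothed `spectra_set`.
#' @export
sg_smooth <- function(spectra, window = 11L, polyorder = 3L) {
  stopifnot(inherits(spectra, "spectra_set"))
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L != 1L) stop("'window' must be odd", call. = FALSE)
  if (polyorder >= window) {
    stop("'polyorder' must be smaller than 'window'", call. = FALSE)
  }
  if (window > ncol(spectra$intensities)) {
    stop("'window' exceeds the channel count", call. = FALSE)
  }
  spectra$intensities <- t(apply(spectra$intensities, 1, function(row) {
    signal::sgolayfilt(row, p = polyorder, n = window)
  }))
  spectra
}

#' Standardize spectra to zero mean and unit standard deviation
#'
#' Per spectrum: subtract the mean and divide by the (sample, n-1)
#' standard deviation. Constant spectra are rejected.
#'
#' @param x numeric spectrum or [spectra_set()].
#' @return standardized object of the same shape.
#' @export
standardize_spectra <- function(x) {
  std1 <- function(v) {
    if (length(v) < 2) stop("at least 2 channels required", call. = FALSE)
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      stop("cannot standardize a constant spectrum", call. = FALSE)
    }
    (v - mean(v)) / s
  }
  if (inherits(x, "spectra_set")) {
    x$intensities <- t(apply(x$intensities, 1, std1))
    return(x)
  }
  std1(x)
}

#' Full spectral preprocessing pipeline
#'
#' Applies, in order: background subtraction (if a background is given),
#' crop to `crop_range`, Savitzky-Golay smoothing, per-spectrum
#' standardization, and selection of the fingerprint `band`. Whether
#' standardization happens on the wide crop (default) or after the band
#' selection is configurable via `standardize_before_band`.
#'
#' @param spectra a [spectra_set()].
#' @param background optional background spectrum on the uncropped axis.
#' @param crop_range initial crop interval, cm^-1.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param band analysis band selected for downstream classification.
#' @param standardize_before_band logical; see Description.
#' @return preprocessed `spectra_set`.
#' @export
preprocess_spectra <- function(spectra, background = NULL,
                               crop_range = c(632, 1862),
                               sg_window = 11L, sg_polyorder = 3L,
                               band = c(700, 1800),
                               standardize_before_band = TRUE) {
  if (!is.null(background)) spectra <- subtract_background(spectra, background)
  spectra <- crop_spectra(spectra, crop_range[1], crop_range[2])
  spectra <- sg_smooth(spectra, sg_window, sg_polyorder)
  if (standardize_before_band) {
    spectra <- standardize_spectra(spectra)
    spectra <- crop_spectra(spectra, band[1], band[2])
  } else {
    spectra <- crop_spectra(spectra, band[1], band[2])
    spectra <- standardize_spectra(spectra)
  }
  spectra
}

#' Write and read spectra as TSV (wavenumber sidecar)
#'
#' The main file has one row per cell (`cell_id`, `condition`, `replicate`,
#' then one column per channel); the wavenumber grid is written to a
#' sidecar file `<path>.wavenumbers.tsv`.
#'
#' @param spectra a [spectra_set()].
#' @param path main TSV path.
#' @return `write_spectra_tsv` returns `path` invisibly;
#'   `read_spectra_tsv` returns a `spectra_set`.
#' @export
write_spectra_tsv <- function(spectra, path) {
  df <- data.frame(cell_id = spectra$cell_id,
                   condition = spectra$condition,
                   replicate = spectra$replicate,
                   spectra$intensities, check.names = FALSE)
  colnames(df)[-(1:3)] <- sprintf("ch%04d", seq_along(spectra$wavenumbers))
  write_tsv(df, path)
  write_tsv(data.frame(wavenumber = spectra$wavenumbers),
            paste0(path, ".wavenumbers.tsv"))
  invisible(path)
}

#' @rdname write_spectra_tsv
#' @export
read_spectra_tsv <- function(path) {
  df <- read_tsv(path)
  wn <- read_tsv(paste0(path, ".wavenumbers.tsv"))$wavenumber
  spectra_set(as.matrix(df[, -(1:3), drop = FALSE]), wn,
              df$condition, df$replicate, cell_id = df$cell_id)
}
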