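#' Standard normal variate (SNV) transform
#'
#' Standardizes one spectrum to mean 0 and unit sample standard deviation
#' (n - 1 denominator), the classical scatter/lighting correction for
#' reflectance spectra. Any per-pixel multiplicative gain or additive offset
#' (a * x + b, a > 0) maps to the same SNV output, which is what makes
#' downstream models robust to lighting gradients.
#'
#' @param x Numeric spectrum, length >= 2, non-constant.
#' @return Standardized spectrum of the same length.
#' @export
snv <- function(x) {
  if (length(x) < 2) stop("SNV needs at least 2 bands, got ", length(x))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("SNV undefined for a constant spectrum (sd = 0); ",
         "degenerate or saturated pixel")
  }
  (x - mean(x)) / s
}

# row-wise SNV for a samples x bands matrix
snv_rows <- function(X) {
  mu <- rowMeans(X)
  s <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
  if (any(s == 0)) stop("SNV undefined for constant spectra in rows: ",
                        paste(which(s == 0), collapse = ", "))
  (X - mu) / s
}

#' Restrict a spectrum to a wavelength range
#'
#' Keeps bands with `lo_nm <= wavelength <= hi_nm` (both inclusive). Used
#' for the VNIR-only (550-900 nm) and extended-NIR-only (900-1700 nm)
#' model variants. Note SNV, when part of a pipeline, must be recomputed on
#' the restricted band set, not inherited from the full spectrum.
#'
#' @param spectrum Numeric spectrum (or samples x bands matrix).
#' @param wavelengths Band grid, nm, same length as the band dimension.
#' @param lo_nm,hi_nm Range bounds, nm, `lo_nm < hi_nm`.
#' @return List with `spectrum` (restricted values) and `wavelengths`
#'   (restricted grid).
#' @export
restrict_range <- function(spectrum, wavelengths, lo_nm, hi_nm) {
  if (lo_nm >= hi_nm) stop("need lo_nm < hi_nm, got [", lo_nm, ", ", hi_nm, "]")
  keep <- wavelengths >= lo_nm & wavelengths <= hi_nm
  if (!any(keep)) {
    stop("no bands fall in [", lo_nm, ", ", hi_nm, "] nm")
  }
  vals <- if (is.matrix(spectrum)) spectrum[, keep, drop = FALSE] else spectrum[keep]
  list(spectrum = vals, wavelengths = wavelengths[keep])
}

#' Subsample bands at a fixed stride
#'
#' Keeps band positions offset, offset + stride, ... (offset is 0-based so
#' that "every 2nd wavelength" with offset 1 on a 235-band grid yields the
#' 117-band set used for the tissue-classification analysis).
#'
#' @param spectrum Numeric spectrum (or samples x bands matrix).
#' @param stride Keep every `stride`-th band; `stride = 1` is the identity.
#' @param offset 0-based offset of the first kept band, `0 <= offset < stride`.
#' @return Subsampled spectrum (or matrix). Use [subsample_index()] for the
#'   kept positions.
#' @export
subsample_bands <- function(spectrum, stride = 2L, offset = 1L) {
  nb <- if (is.matrix(spectrum)) ncol(spectrum) else length(spectrum)
  idx <- subsample_index(nb, stride, offset)
  if (is.matrix(spectrum)) spectrum[, idx, drop = FALSE] else spectrum[idx]
}

#' @rdname subsample_bands
#' @param n_bands Number of bands in the full grid.
#' @export
subsample_index <- function(n_bands, stride = 2L, offset = 1L) {
  stride <- as.integer(stride); offset <- as.integer(offset)
  if (stride < 1) stop("stride must be >= 1")
  if (offset < 0 || offset >= stride) stop("need 0 <= offset < stride")
  seq.int(offset + 1L, n_bands, by = stride)
}
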