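#' Segment plant pixels by reflectance threshold
#'
#' The plant region of interest is defined as pixels with reflectance
#' >= `threshold_r` at the band nearest `threshold_nm` (default 0.3 at
#' 1080 nm, a wavelength little affected by water content). Pixels whose
#' calibration was invalid are never selected.
#'
#' @param cube A `reflectance_cube`.
#' @param threshold_r Reflectance cutoff (inclusive).
#' @param threshold_nm Wavelength used for thresholding, nm.
#' @return An `roi_mask`: `mask` (line x sample logical), `n_pixels`,
#'   `threshold_nm`, `threshold_r`.
#' @export
segment <- function(cube, threshold_r = 0.3, threshold_nm = 1080) {
  b <- band_index(cube$wavelengths, threshold_nm)
  plane <- cube$reflectance[, , b]
  mask <- plane >= threshold_r & !cube$invalid_mask
  structure(list(mask = mask, n_pixels = sum(mask),
                 threshold_nm = threshold_nm, threshold_r = threshold_r),
            class = "roi_mask")
}

#' Mean spectrum over a mask
#'
#' Per-band arithmetic mean of the reflectance over the masked pixels.
#'
#' @param cube A `reflectance_cube`.
#' @param mask An `roi_mask` (or a logical line x sample matrix).
#' @return List with `spectrum` (length = bands), `n_pixels`, `wavelengths`.
#' @export
mean_spectrum <- function(cube, mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  stopifnot(all(dim(m) == dim(cube$reflectance)[1:2]))
  k <- sum(m)
  if (k == 0) stop("empty mask: segmentation selected no pixels")
  nb <- dim(cube$reflectance)[3]
  flat <- matrix(cube$reflectance, ncol = nb)   # (line*sample) x band
  spec <- colMeans(flat[as.vector(m), , drop = FALSE])
  list(spectrum = spec, n_pixels = k, wavelengths = cube$wavelengths)
}

#' Aggregate replicate images into one plant spectrum
#'
#' Averages the 1-3 replicate mean spectra of a plant (unweighted) and
#' applies the pixel-count exclusion rule: a plant whose replicate-average
#' ROI pixel count falls below `min_pixels` is flagged excluded (not an
#' error) and takes no part in modelling.
#'
#' @param replicates List of replicate summaries, each with `spectrum` and
#'   `n_pixels` (as returned by [mean_spectrum()]).
#' @param min_pixels Exclusion threshold on the replicate-average pixel
#'   count (boundary inclusive: exactly `min_pixels` is retained).
#' @param plant_id,tissue Provenance labels ("PS", "BL" or "whole").
#' @return A `plant_spectrum`: `plant_id`, `tissue`, `spectrum`,
#'   `n_pixels_mean`, `n_images`, and `excluded` (logical).
#' @export
aggregate_plant <- function(replicates, min_pixels = 5000,
                            plant_id = NA, tissue = "whole") {
  n <- length(replicates)
  if (n == 0) stop("no replicate images supplied")
  if (n > 3) stop("at most 3 replicate images per plant, got ", n)
  specs <- do.call(rbind, lapply(replicates, function(r) r$spectrum))
  spectrum <- colMeans(specs)
  n_pixels_mean <- mean(vapply(replicates, function(r) r$n_pixels, numeric(1)))
  structure(list(plant_id = plant_id, tissue = tissue,
                 spectrum = spectrum, n_pixels_mean = n_pixels_mean,
                 n_images = n, excluded = n_pixels_mean < min_pixels),
            class = "plant_spectrum")
}

#' Export an ROI mask
#'
#' Writes the mask as an 8-bit PNG (0 background / 255 plant) or as a flat
#' CSV of selected (line, sample) coordinates.
#'
#' @param mask An `roi_mask`.
#' @param path Output file path; format chosen by extension (.png or .csv).
#' @export
write_mask <- function(mask, path) {
  m <- mask$mask
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m * 1, path)
  } else {
    idx <- which(m, arr.ind = TRUE)
    utils::write.csv(data.frame(line = idx[, 1], sample = idx[, 2]),
                     path, row.names = FALSE)
  }
  invisible(path)
}
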