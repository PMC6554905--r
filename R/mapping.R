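#' Per-pixel trait map from a plant-level model
#'
#' Applies a calibration fitted on plant-level mean spectra to every pixel
#' of a reflectance cube: each pixel spectrum gets the same preprocessing
#' as the calibration spectra (SNV by default, optional range restriction /
#' band subsampling) and is pushed through the model. Background pixels
#' (below the segmentation threshold) and pixels with very low mean
#' reflectance are masked and carry NA.
#'
#' Because SNV standardizes each pixel spectrum individually, the map is
#' invariant to the multiplicative lighting gradient of the acquisition.
#' Applying a plant-level calibration at pixel scale is a calibration
#' transfer and carries its own bias for pixels unlike any calibration
#' spectrum; zone averages remain well behaved.
#'
#' @param cube A `reflectance_cube`.
#' @param model A fitted `pls_model`.
#' @param pipeline Preprocessing descriptor, list with `snv` (logical),
#'   optional `range_nm` (c(lo, hi)), optional `stride`/`offset`.
#'   Must match the pipeline the model was calibrated with.
#' @param low_reflectance_cutoff Pixels whose mean reflectance over bands
#'   falls below this are masked (default 0.05).
#' @param threshold_r,threshold_nm Segmentation rule for the background mask.
#' @return A `trait_map`: `values` (line x sample, NA where masked),
#'   `masked` (logical matrix), plus the pipeline record.
#' @export
predict_map <- function(cube, model, pipeline = list(snv = TRUE),
                        low_reflectance_cutoff = 0.05,
                        threshold_r = 0.3, threshold_nm = 1080) {
  nb <- dim(cube$reflectance)[3]
  mask <- segment(cube, threshold_r, threshold_nm)$mask
  nl <- dim(cube$reflectance)[1]; ns <- dim(cube$reflectance)[2]
  flat <- matrix(cube$reflectance, ncol = nb)
  low <- rowMeans(flat) < low_reflectance_cutoff
  use <- as.vector(mask) & !low

  values <- matrix(NA_real_, nl, ns)
  if (any(use)) {
    pre <- pipeline; pre$snv <- FALSE
    Xp <- preprocess_matrix(flat[use, , drop = FALSE], cube$wavelengths, pre)
    if (isTRUE(pipeline$snv)) {
      # constant pixel spectra (saturated/flat) have no SNV; mask them
      sds <- apply(Xp, 1, stats::sd)
      keep <- sds > 0
      if (!all(keep)) {
        use[which(use)[!keep]] <- FALSE
        Xp <- Xp[keep, , drop = FALSE]
      }
      if (nrow(Xp) > 0) Xp <- snv_rows(Xp)
    }
    if (ncol(Xp) != length(model$x_mean)) {
      stop("band mismatch after preprocessing: model has ",
           length(model$x_mean), " bands, pixels have ", ncol(Xp))
    }
    if (nrow(Xp) > 0) values[use] <- predict(model, Xp)
  }
  structure(list(values = values, masked = matrix(!use, nl, ns),
                 pipeline = pipeline,
                 cutoff = low_reflectance_cutoff),
            class = "trait_map")
}

# shared preprocessing of a samples x bands matrix per a pipeline record
preprocess_matrix <- function(X, wavelengths, pipeline) {
  if (!is.null(pipeline$range_nm)) {
    res <- restrict_range(X, wavelengths, pipeline$range_nm[1], pipeline$range_nm[2])
    X <- res$spectrum; wavelengths <- res$wavelengths
  }
  if (!is.null(pipeline$stride) && pipeline$stride > 1) {
    off <- if (is.null(pipeline$offset)) 1L else pipeline$offset
    X <- subsample_bands(X, pipeline$stride, off)
  }
  if (isTRUE(pipeline$snv)) X <- snv_rows(X)
  X
}

#' False-color composite of a cube
#'
#' Three-channel rendering of the cube at the visualization wavelengths
#' (defaults 558, 740 and 937 nm), each channel min-max scaled to [0, 1]
#' over valid pixels. A zero-range channel maps to 0.
#'
#' @param cube A `reflectance_cube`.
#' @param bands_nm Three wavelengths, nm.
#' @return Array (lines, samples, 3) in [0, 1].
#' @export
false_color <- function(cube, bands_nm = c(558, 740, 937)) {
  stopifnot(length(bands_nm) == 3)
  idx <- vapply(bands_nm, function(nm) band_index(cube$wavelengths, nm), 1L)
  nl <- dim(cube$reflectance)[1]; ns <- dim(cube$reflectance)[2]
  out <- array(0, dim = c(nl, ns, 3))
  valid <- !cube$invalid_mask
  for (ch in 1:3) {
    plane <- cube$reflectance[, , idx[ch]]
    v <- plane[valid]
    rng <- range(v)
    scaled <- if (diff(rng) == 0) matrix(0, nl, ns) else (plane - rng[1]) / diff(rng)
    scaled[!valid] <- 0
    out[, , ch] <- pmin(pmax(scaled, 0), 1)
  }
  out
}

#' Write a trait map to disk
#'
#' CSV grid of predicted values (NA for masked pixels) and, for `.png`
#' paths, a grayscale render with masked pixels white.
#'
#' @param map A `trait_map`.
#' @param path Output path (.csv or .png).
#' @export
write_trait_map <- function(map, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    v <- map$values
    rng <- range(v, na.rm = TRUE)
    g <- if (diff(rng) == 0) (v * 0) else (v - rng[1]) / diff(rng)
    g[is.na(g)] <- 1  # masked pixels render white
    png::writePNG(g, path)
  } else {
    utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, na = "")
  }
  invisible(path)
}
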