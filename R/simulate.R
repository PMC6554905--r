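#' Scene configuration for the cube generator
#'
#' Defaults follow the line-scan instrument geometry: 400 lines of 320
#' samples, 235 bands over 550-1700 nm (128,000 pixel spectra per image).
#' `lighting_gradient` is the strength of a multiplicative linear ramp along
#' the line axis (the along-track illumination falloff of a single-beam
#' source); `noise_sd` is additive Gaussian sensor noise on the reflectance
#' scale.
#'
#' @param lines,samples,bands Cube dimensions.
#' @param plant_fraction Target foreground fraction of pixels, in (0, 1).
#' @param lighting_gradient Peak-to-center relative ramp amplitude
#'   (0 disables; 0.2 means +/-10\% across the image).
#' @param noise_sd Additive reflectance noise SD.
#' @param seed Integer seed; identical configuration gives a bit-identical
#'   scene.
#' @export
scene_config <- function(lines = 400L, samples = 320L, bands = 235L,
                         plant_fraction = 0.35, lighting_gradient = 0.2,
                         noise_sd = 0.01, seed = 1L) {
  if (plant_fraction <= 0 || plant_fraction >= 1) {
    stop("plant_fraction must lie strictly inside (0, 1)")
  }
  if (lines < 1 || samples < 1 || bands < 1) stop("all dimensions must be positive")
  structure(list(lines = as.integer(lines), samples = as.integer(samples),
                 bands = as.integer(bands), plant_fraction = plant_fraction,
                 lighting_gradient = lighting_gradient, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Generate one synthetic hyperspectral acquisition
#'
#' Builds a raw irradiance cube plus white/dark reference frames for a
#' single plant. Foreground pixels (an elliptical blob covering exactly
#' `round(plant_fraction * lines * samples)` pixels) carry the tissue
#' reflectance of the plant's attribute concentrations (see
#' [endmember_library()]), modulated by the lighting ramp, with additive
#' sensor noise; background pixels carry a flat low-reflectance baseline
#' that stays below the 0.3 segmentation threshold at 1080 nm. The raw
#' irradiance is reconstructed as `I = R * (W - D) + D`, so white/dark
#' calibration inverts the forward model exactly (to the noise realization).
#'
#' @param attributes Named list or one-row data.frame of attribute
#'   concentrations for this plant (names must cover every attribute the
#'   library's features reference).
#' @param library An [endmember_library()].
#' @param scene A [scene_config()]; `scene$bands` must match the library grid.
#' @param tissue `"BL"` or `"PS"`: which baseline the foreground carries.
#' @return List with `raw` (a `raw_cube` of irradiance), `refs`
#'   (a `reference_pair`), `truth_mask` (logical line x sample foreground
#'   mask), `reflectance` (the forward-model `reflectance_cube`, including
#'   noise), and `wavelengths`.
#' @export
generate_cube <- function(attributes, library, scene, tissue = "BL") {
  stopifnot(inherits(library, "endmember_library"), inherits(scene, "scene_config"))
  if (scene$bands != length(library$wavelengths)) {
    stop("scene$bands (", scene$bands, ") != library grid length (",
         length(library$wavelengths), ")")
  }
  zones <- list(list(tissue = tissue, attributes = attributes, rows = NULL))
  build_scene(zones, library, scene)
}

#' Generate a two-zone plant scene (pseudostem base, blade top)
#'
#' Like [generate_cube()] but the lower half of the foreground blob carries
#' the pseudostem spectrum and the upper half the blade spectrum, emulating
#' a whole plant photographed from above with sugar-rich pseudostems at the
#' base of the sward. Used to test per-pixel trait maps against ground
#' truth.
#'
#' @param ps_attributes,bl_attributes Attribute rows for the two zones.
#' @inheritParams generate_cube
#' @return As [generate_cube()], plus `zone` (character line x sample matrix:
#'   "PS", "BL" or "background").
#' @export
generate_two_zone_cube <- function(ps_attributes, bl_attributes, library, scene) {
  zones <- list(list(tissue = "PS", attributes = ps_attributes, rows = "lower"),
                list(tissue = "BL", attributes = bl_attributes, rows = "upper"))
  build_scene(zones, library, scene)
}

build_scene <- function(zones, library, scene) {
  set.seed(scene$seed)
  nl <- scene$lines; ns <- scene$samples; nb <- scene$bands
  npix <- nl * ns
  n_fg <- round(scene$plant_fraction * npix)
  if (n_fg == 0 || n_fg == npix) {
    stop("plant_fraction leaves no foreground or no background pixel")
  }

  # elliptical blob, exact pixel count via rank thresholding
  li <- matrix(seq_len(nl), nl, ns)
  si <- matrix(seq_len(ns), nl, ns, byrow = TRUE)
  field <- ((li - (nl + 1) / 2) / nl)^2 + ((si - (ns + 1) / 2) / ns)^2
  cutoff <- sort(as.vector(field), partial = n_fg)[n_fg]
  mask <- field <= cutoff
  # resolve ties at the cutoff deterministically
  if (sum(mask) > n_fg) {
    excess <- which(as.vector(field) == cutoff)
    drop <- excess[seq_len(sum(mask) - n_fg)]
    mask[drop] <- FALSE
  }

  zone <- matrix("background", nl, ns)
  if (length(zones) == 1) {
    zone[mask] <- zones[[1]]$tissue
  } else {
    mid <- (nl + 1) / 2
    for (z in zones) {
      sel <- if (z$rows == "lower") mask & li > mid else mask & li <= mid
      zone[sel] <- z$tissue
    }
  }

  # per-pixel reflectance: base spectrum by zone x lighting ramp + noise
  ramp <- 1 + scene$lighting_gradient * ((seq_len(nl) - 1) / max(nl - 1, 1) - 0.5)
  ramp_pix <- as.vector(matrix(ramp, nl, ns))        # pixel-major (line fastest)

  flat <- matrix(0, npix, nb)
  bg_spec <- library$baseline$background
  flat[] <- outer(ramp_pix, bg_spec)
  for (z in zones) {
    sel <- as.vector(zone == z$tissue)
    if (!any(sel)) next
    spec <- tissue_reflectance(library, as.list(z$attributes), z$tissue)
    flat[sel, ] <- outer(ramp_pix[sel], spec)
  }
  if (scene$noise_sd > 0) {
    flat <- flat + stats::rnorm(length(flat), sd = scene$noise_sd)
  }

  # references: flat white frame, dark frame with small positive offset + noise
  W <- matrix(4000, ns, nb)
  D <- matrix(50 + abs(stats::rnorm(ns * nb, sd = 2)), ns, nb)

  R <- array(flat, dim = c(nl, ns, nb))
  Dl <- aperm(array(D, dim = c(ns, nb, nl)), c(3, 1, 2))
  Wl <- aperm(array(W, dim = c(ns, nb, nl)), c(3, 1, 2))
  I <- R * (Wl - Dl) + Dl

  list(raw = raw_cube(I, library$wavelengths,
                      meta = list(generator = "grasshsi", seed = scene$seed)),
       refs = reference_pair(W, D),
       truth_mask = mask,
       zone = zone,
       reflectance = reflectance_cube(R, library$wavelengths),
       wavelengths = library$wavelengths)
}

#' Write a simulated acquisition to disk
#'
#' Writes the raw cube as ENVI (header + band-interleaved-by-line binary)
#' plus white/dark reference frames (each as a single-line ENVI cube) and
#' the ground-truth mask as CSV.
#'
#' @param sim Output of [generate_cube()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @export
write_simulated_scene <- function(sim, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_envi(sim$raw, file.path(dir, stem), interleave = "bil")
  wl <- sim$wavelengths
  ref_cube <- function(m) list(irradiance = array(m, dim = c(1, nrow(m), ncol(m))),
                               wavelengths = wl)
  write_envi(ref_cube(sim$refs$white), file.path(dir, paste0(stem, "_white")))
  write_envi(ref_cube(sim$refs$dark), file.path(dir, paste0(stem, "_dark")))
  idx <- which(sim$truth_mask, arr.ind = TRUE)
  utils::write.csv(data.frame(line = idx[, 1], sample = idx[, 2]),
                   file.path(dir, paste0(stem, "_mask.csv")), row.names = FALSE)
  invisible(dir)
}
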