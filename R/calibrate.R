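#' Radiometric calibration from white/dark references
#'
#' Converts raw irradiance counts to reflectance with
#' \deqn{R = (I - D) / (W - D)}
#' where `W` and `D` are the white (Spectralon tile) and dark (lens cap)
#' reference frames. For a line-scan instrument the references are one frame
#' of shape (sample, band), broadcast along the line axis; scalar-per-band or
#' full (line, sample, band) references are also accepted.
#'
#' Reflectance is deliberately not clipped to [0, 1]: bright specular tissue
#' can legitimately exceed the white tile. Pixels where `W - D <= 0` have no
#' defined reflectance; they are flagged in `invalid_mask` and carry 0 so the
#' array stays finite.
#'
#' @param raw A `raw_cube` (see [read_envi()]).
#' @param refs A `reference_pair`: list with `white` and `dark`, each a
#'   (sample x band) matrix (or scalar/vector recycled to that shape).
#' @return A `reflectance_cube`: `reflectance` (line x sample x band),
#'   `wavelengths`, and `invalid_mask` (line x sample, TRUE where any band's
#'   calibration was undefined).
#' @export
calibrate <- function(raw, refs) {
  arr <- raw$irradiance
  d <- dim(arr)
  nl <- d[1]; ns <- d[2]; nb <- d[3]
  W <- expand_reference(refs$white, ns, nb, "white")
  D <- expand_reference(refs$dark, ns, nb, "dark")

  denom <- W - D
  bad_ref <- denom <= 0              # (sample, band)
  denom[bad_ref] <- 1                # placeholder; flagged below

  # broadcast (sample, band) along lines
  Dl <- aperm(array(D, dim = c(ns, nb, nl)), c(3, 1, 2))
  denoml <- aperm(array(denom, dim = c(ns, nb, nl)), c(3, 1, 2))
  R <- (arr - Dl) / denoml

  invalid <- matrix(FALSE, nl, ns)
  if (any(bad_ref)) {
    bad_sample <- apply(bad_ref, 1, any)
    invalid[, bad_sample] <- TRUE
    badl <- aperm(array(bad_ref, dim = c(ns, nb, nl)), c(3, 1, 2))
    R[badl] <- 0
  }
  reflectance_cube(R, raw$wavelengths, invalid_mask = invalid)
}

#' Construct a reflectance cube
#'
#' @param reflectance 3-D array (line, sample, band).
#' @param wavelengths Strictly increasing band grid in nm.
#' @param invalid_mask Optional (line, sample) logical matrix of pixels whose
#'   calibration was undefined; defaults to all-valid.
#' @export
reflectance_cube <- function(reflectance, wavelengths, invalid_mask = NULL) {
  stopifnot(length(dim(reflectance)) == 3,
            length(wavelengths) == dim(reflectance)[3])
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelength grid must be strictly increasing")
  }
  if (is.null(invalid_mask)) {
    invalid_mask <- matrix(FALSE, dim(reflectance)[1], dim(reflectance)[2])
  }
  stopifnot(all(dim(invalid_mask) == dim(reflectance)[1:2]))
  if (any(!is.finite(reflectance))) stop("reflectance contains non-finite values")
  structure(list(reflectance = reflectance,
                 wavelengths = as.numeric(wavelengths),
                 invalid_mask = invalid_mask),
            class = "reflectance_cube")
}

#' Reference pair constructor
#'
#' @param white,dark (sample x band) matrices of reference counts.
#' @export
reference_pair <- function(white, dark) {
  structure(list(white = white, dark = dark), class = "reference_pair")
}

expand_reference <- function(ref, ns, nb, name) {
  if (is.null(ref)) stop("missing ", name, " reference")
  if (length(ref) == 1) return(matrix(ref, ns, nb))
  if (is.null(dim(ref)) && length(ref) == nb) {
    return(matrix(ref, ns, nb, byrow = TRUE))
  }
  if (!is.matrix(ref) || nrow(ref) != ns || ncol(ref) != nb) {
    stop(name, " reference shape incompatible: need (", ns, " samples x ",
         nb, " bands)")
  }
  ref
}

#' Band nearest a target wavelength
#'
#' Index (1-based) of the band whose wavelength is nearest `target_nm`;
#' exact midpoints resolve to the lower wavelength. Targets more than one
#' grid spacing outside the grid are rejected.
#'
#' @param wavelengths Band grid, nm.
#' @param target_nm Target wavelength, nm.
#' @export
band_index <- function(wavelengths, target_nm) {
  n <- length(wavelengths)
  if (n == 0) stop("empty wavelength grid")
  if (n > 1) {
    delta <- max(diff(wavelengths))
    if (target_nm < wavelengths[1] - delta || target_nm > wavelengths[n] + delta) {
      stop("target ", target_nm, " nm outside grid range [",
           wavelengths[1], ", ", wavelengths[n], "] +/- ", delta, " nm")
    }
  }
  dist <- abs(wavelengths - target_nm)
  # which.min already takes the first (= lower-wavelength) minimum on ties
  which.min(dist)
}
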