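#' Spectral endmember library for the scene generator
#'
#' Defines the forward optical model: a baseline reflectance spectrum per
#' tissue (pseudostem, blade, background) on the instrument's
#' 235-band grid (550-1700 nm), plus Gaussian absorption features tied to
#' attribute concentrations. Foreground reflectance is
#' \deqn{R(\lambda) = baseline(\lambda) \exp(-\sum_f a_f c_{attr(f)} G_f(\lambda))}
#' a Beer-Lambert-style attenuation: smooth, monotone in concentration and
#' invertible, which is the structure latent-variable regression assumes.
#'
#' Baselines reproduce the qualitative shape of ryegrass reflectance:
#' low visible reflectance, a red-edge rise to a NIR plateau, and water
#' absorption minima at 1000, 1200 and 1450 nm; the pseudostem baseline sits
#' higher at 800-1100 nm and lower at 1200-1500 nm than the blade baseline.
#' Feature centers for nitrogen and the sugar fractions fall inside the
#' wavelength regions that drive their prediction (around 560, 640-750,
#' 890, 935, 1350-1460 and 1510-1700 nm).
#'
#' @param wavelengths Band grid in nm (default: 235 bands, 550-1700 nm).
#' @param encoding `"beer_lambert"` (default): exponential attenuation as
#'   above; `"linear"`: first-order expansion
#'   `R = baseline * (1 - sum a_f c G_f)`, which makes foreground spectra
#'   exactly affine in the concentrations — useful for closed-loop identity
#'   tests where latent-variable regression must recover the response to
#'   machine precision.
#' @return An `endmember_library`: `wavelengths`, `baseline` (named list of
#'   per-tissue spectra), `features` (data.frame: attribute, center_nm,
#'   width_nm, amplitude per unit concentration).
#' @export
endmember_library <- function(wavelengths = seq(550, 1700, length.out = 235),
                              encoding = c("beer_lambert", "linear")) {
  encoding <- match.arg(encoding)
  wl <- as.numeric(wavelengths)
  if (is.unsorted(wl, strictly = TRUE)) stop("wavelength grid must be strictly increasing")

  gauss <- function(center, width) exp(-0.5 * ((wl - center) / width)^2)
  red_edge <- 1 / (1 + exp(-(wl - 710) / 18))
  water_dips <- function(d1, d2, d3) {
    d1 * gauss(1000, 30) + d2 * gauss(1200, 40) + d3 * gauss(1450, 45)
  }

  baseline_bl <- 0.22 + 0.42 * red_edge - water_dips(0.06, 0.12, 0.27)
  baseline_ps <- 0.26 + 0.56 * red_edge - water_dips(0.05, 0.22, 0.45) +
    0.10 * gauss(950, 120)
  baseline_bg <- rep(0.08, length(wl))

  features <- rbind(
    feat("nitrogen", 560,  15, 0.030), feat("nitrogen", 700, 25, 0.030),
    feat("nitrogen", 890,   6, 0.025), feat("nitrogen", 935,  6, 0.025),
    feat("nitrogen", 1380, 30, 0.030), feat("nitrogen", 1600, 55, 0.025),
    feat("sugars",   565,  10, 0.0008), feat("sugars",  705, 20, 0.0008),
    feat("sugars",  1400,  35, 0.0012), feat("sugars", 1590, 30, 0.0010),
    feat("hmw",     1360,  22, 0.0012), feat("hmw",    1680, 15, 0.0010),
    feat("lmw",      645,  15, 0.0012), feat("lmw",    1530, 20, 0.0012),
    feat("ndf",     1210,  30, 0.0020), feat("ndf",    1490, 25, 0.0018),
    feat("adf",     1230,  20, 0.0020),
    feat("ash",      600,  30, 0.0040), feat("ash",    1150, 40, 0.0035),
    feat("ca",       870,  15, 0.0080),
    feat("domd",    1140,  25, 0.0015),
    feat("me",      1040,  20, 0.0100),
    feat("dm",       970,  25, 0.0010),
    feat("om",      1270,  25, 0.0012)
  )
  bad <- features$center_nm < min(wl) | features$center_nm > max(wl)
  if (any(bad)) stop("feature centers outside the wavelength grid")

  structure(list(wavelengths = wl,
                 baseline = list(BL = baseline_bl, PS = baseline_ps,
                                 background = baseline_bg),
                 features = features, encoding = encoding),
            class = "endmember_library")
}

feat <- function(attribute, center_nm, width_nm, amplitude) {
  data.frame(attribute = attribute, center_nm = center_nm,
             width_nm = width_nm, amplitude = amplitude,
             stringsAsFactors = FALSE)
}

# tissue reflectance spectrum for one set of attribute concentrations
tissue_reflectance <- function(library, attributes, tissue) {
  base <- library$baseline[[tissue]]
  if (is.null(base)) stop("unknown tissue '", tissue, "'")
  wl <- library$wavelengths
  absorb <- numeric(length(wl))
  fts <- library$features
  for (i in seq_len(nrow(fts))) {
    conc <- attributes[[fts$attribute[i]]]
    if (is.null(conc) || is.na(conc)) {
      stop("attribute '", fts$attribute[i], "' required by the endmember ",
           "library is missing from the attribute row")
    }
    absorb <- absorb + fts$amplitude[i] * conc *
      exp(-0.5 * ((wl - fts$center_nm[i]) / fts$width_nm[i])^2)
  }
  if (identical(library$encoding, "linear")) base * (1 - absorb) else base * exp(-absorb)
}
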