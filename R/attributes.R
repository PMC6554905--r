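#' Attribute population specification
#'
#' One row of the population model for a forage-quality attribute: location
#' and spread on the attribute's own scale, the hard range values are
#' clipped to, and the pseudostem/blade coupling (mean offset and squared
#' correlation) used when tissue-resolved values are simulated.
#'
#' `ps_bl_shift` is the PS-minus-BL mean offset: negative for attributes
#' that concentrate in the blades (nitrogen), positive for those that
#' concentrate in the pseudostems (sugars).
#'
#' @param name Attribute identifier.
#' @param units Unit string ("mg/g", "\%", "MJ/kg DM").
#' @param mean,sd Population mean and SD (sd > 0).
#' @param min,max Clipping range (min < max).
#' @param ps_bl_shift PS - BL mean offset on the attribute scale.
#' @param ps_bl_r2 Squared PS~BL correlation, in [0, 1].
#' @export
attribute_spec <- function(name, units, mean, sd, min, max,
                           ps_bl_shift = 0, ps_bl_r2 = 0.6) {
  if (!is.finite(sd) || sd <= 0) {
    stop("attribute '", name, "': sd must be > 0, got ", sd)
  }
  if (min >= max) stop("attribute '", name, "': need min < max")
  if (ps_bl_r2 < 0 || ps_bl_r2 > 1) {
    stop("attribute '", name, "': ps_bl_r2 must lie in [0, 1]")
  }
  structure(list(name = name, units = units, mean = mean, sd = sd,
                 min = min, max = max, ps_bl_shift = ps_bl_shift,
                 ps_bl_r2 = ps_bl_r2),
            class = "attribute_spec")
}

#' Default forage attribute specifications
#'
#' Population parameters for the 13 ryegrass forage-quality attributes:
#' min/max/mean/SD taken from the validation-set summaries of the combined
#' blades + pseudostems dataset, PS/BL offsets and couplings from the
#' 15-plant tissue-resolved subset (nitrogen 1.1% higher in blades; sugars
#' strongly concentrated in pseudostems; PS~BL R-squared 0.50-0.89 for the
#' sugar fractions and nitrogen). Attributes without reported tissue
#' contrasts get no offset and a moderate default coupling.
#'
#' @return Named list of [attribute_spec()] objects in standard table order.
#' @export
default_attribute_specs <- function() {
  sp <- list(
    attribute_spec("lmw",          "mg/g",     54.1, 20.3, 23.0, 121.3, ps_bl_shift = 34,   ps_bl_r2 = 0.50),
    attribute_spec("hmw",          "mg/g",     37.1, 35.0,  3.1, 144.1, ps_bl_shift = 58,   ps_bl_r2 = 0.89),
    attribute_spec("sugars",       "mg/g",     91.5, 52.8, 27.1, 244.5, ps_bl_shift = 93,   ps_bl_r2 = 0.84),
    attribute_spec("visual_yield", "%",        20.3,  3.3, 14.6,  25.9),
    attribute_spec("ndf",          "%",        45.9,  3.3, 38.7,  53.8),
    attribute_spec("adf",          "%",        25.9,  2.1, 21.6,  30.2),
    attribute_spec("nitrogen",     "%",        3.21,  0.6,  1.6,  4.72, ps_bl_shift = -1.1, ps_bl_r2 = 0.83),
    attribute_spec("domd",         "% DM",     65.3,  1.7, 61.2,  69.2),
    attribute_spec("me",           "MJ/kg DM", 10.4,  0.3,  9.8,  11.1),
    attribute_spec("dm",           "%",        94.5,  0.7, 93.0,  96.2),
    attribute_spec("ash",          "%",         9.9,  1.1,  6.5,  12.2),
    attribute_spec("ca",           "mg/g",      4.3,  1.0,  2.5,   7.2),
    attribute_spec("om",           "%",        84.6,  1.4, 81.2,  88.4)
  )
  stats::setNames(sp, vapply(sp, `[[`, "", "name"))
}

#' Simulate a plant attribute table
#'
#' Draws per-plant attribute values with the tissue structure the analysis
#' assumes: for each plant and attribute, PS and BL values come from a
#' bivariate normal with correlation `sqrt(ps_bl_r2)`, means offset by
#' `ps_bl_shift`, and a common variance inflation chosen so the
#' tissue-fraction-weighted whole-plant value has exactly the spec SD. All
#' values are clipped to the spec range (tissue values to the range shifted
#' by that tissue's mean offset).
#'
#' Because clipping a normal sample to [min, max] shrinks its spread, the
#' generator first solves for latent (mean, sd) such that the clipped
#' (censored-normal) distribution has exactly the spec mean and SD; wide
#' attributes such as the high-molecular-weight sugars would otherwise lose
#' a large part of their variance at the range boundary.
#'
#' @param specs List of [attribute_spec()]s (default [default_attribute_specs()]).
#' @param n_plants Number of plants (>= 2).
#' @param seed Integer random seed; identical inputs give identical tables.
#' @param tissue_fraction Pseudostem mass fraction used for the whole-plant
#'   weighted mean (default 0.5).
#' @return A data.frame with one row per plant per tissue
#'   (`whole`, `PS`, `BL`); columns `plant_id`, `tissue`, then one column
#'   per attribute in spec order.
#' @export
generate_attribute_table <- function(specs = default_attribute_specs(),
                                     n_plants, seed = 1L,
                                     tissue_fraction = 0.5) {
  if (length(specs) == 0) stop("specs must be non-empty")
  if (n_plants < 2) stop("n_plants must be >= 2, got ", n_plants)
  for (sp in specs) {
    if (!inherits(sp, "attribute_spec")) stop("all specs must be attribute_spec objects")
  }
  set.seed(as.integer(seed))
  w <- tissue_fraction
  out <- data.frame(
    plant_id = rep(paste0("plant_", sprintf("%03d", seq_len(n_plants))), 3),
    tissue = rep(c("whole", "PS", "BL"), each = n_plants),
    stringsAsFactors = FALSE
  )
  for (sp in specs) {
    rho <- sqrt(sp$ps_bl_r2)
    lat <- censored_normal_params(sp$mean, sp$sd, sp$min, sp$max)
    # inflate tissue SD so whole = w*PS + (1-w)*BL has SD exactly lat["sd"]
    infl <- 1 / sqrt(w^2 + (1 - w)^2 + 2 * w * (1 - w) * rho)
    z1 <- stats::rnorm(n_plants)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_plants)
    ps <- lat[["mean"]] + w_shift(sp$ps_bl_shift, w, "PS") + infl * lat[["sd"]] * z1
    bl <- lat[["mean"]] + w_shift(sp$ps_bl_shift, w, "BL") + infl * lat[["sd"]] * z2
    whole <- w * ps + (1 - w) * bl
    ps <- clip(ps, sp$min + w_shift(sp$ps_bl_shift, w, "PS"),
                   sp$max + w_shift(sp$ps_bl_shift, w, "PS"))
    bl <- clip(bl, sp$min + w_shift(sp$ps_bl_shift, w, "BL"),
                   sp$max + w_shift(sp$ps_bl_shift, w, "BL"))
    whole <- clip(whole, sp$min, sp$max)
    out[[sp$name]] <- c(whole, ps, bl)
  }
  attr(out, "tissue_fraction") <- w
  attr(out, "seed") <- as.integer(seed)
  out
}

# mean offset of one tissue so the w-weighted whole sits at the spec mean
w_shift <- function(shift, w, tissue) {
  if (tissue == "PS") (1 - w) * shift else -w * shift
}

# moments of clip(Z, a, b) with Z ~ N(mu, sigma), closed form
censored_normal_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Fa <- stats::pnorm(al); Fb <- stats::pnorm(be)
  fa <- stats::dnorm(al); fb <- stats::dnorm(be)
  pm <- Fb - Fa
  m1 <- a * Fa + b * (1 - Fb) + mu * pm - sigma * (fb - fa)
  m2 <- a^2 * Fa + b^2 * (1 - Fb) +
    mu^2 * pm + 2 * mu * sigma * (fa - fb) +
    sigma^2 * (pm + al * fa - be * fb)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# latent (mean, sd) whose censored distribution has the target moments
censored_normal_params <- function(mean, sd, a, b) {
  # negligible spread relative to the range: clipping cannot bite
  if (sd < 1e-6 * (b - a)) return(c(mean = mean, sd = sd))
  direct <- censored_normal_moments(mean, sd, a, b)
  if (abs(direct[["mean"]] - mean) < 1e-6 * max(sd, 1e-12) &&
      abs(direct[["sd"]] - sd) < 1e-6 * max(sd, 1e-12)) {
    return(c(mean = mean, sd = sd))
  }
  obj <- function(par) {
    m <- censored_normal_moments(par[1], exp(par[2]), a, b)
    (m[["mean"]] - mean)^2 / sd^2 + (m[["sd"]] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-8) {
    warning("censored-normal moment match imperfect (min ", a, ", max ", b,
            "): residual ", format(sqrt(fit$value), digits = 3))
  }
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Write an attribute table as CSV
#'
#' Header row: `plant_id`, `tissue`, then the attribute columns in standard
#' table order.
#'
#' @param table Output of [generate_attribute_table()].
#' @param path Output CSV path.
#' @export
write_attribute_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
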