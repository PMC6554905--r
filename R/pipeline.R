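#' Study configuration
#'
#' Describes one desk-scale synthetic study: population size and tissue
#' subset, attributes to model, dataset variant, wavelength range, methods,
#' replicate imaging, scene geometry and the seeds of every random stage.
#'
#' The default scene is a reduced-geometry acquisition (80 lines x 64
#' samples) with the instrument's 235-band grid; the pixel-count exclusion
#' threshold is scaled by the area ratio to the full 400 x 320 frame so the
#' rule bites at the same relative plant size. Noise and lighting-gradient
#' defaults are those of [scene_config()].
#'
#' @param n_plants Plants in the study (default 185).
#' @param n_tissue_plants Plants with separate PS and BL acquisitions
#'   (default 15).
#' @param attributes Attribute names to model.
#' @param dataset `"BL+PS"` (blade samples of every plant plus the
#'   pseudostem samples of the tissue subset) or `"BL"`.
#' @param range_nm Optional c(lo, hi) wavelength restriction.
#' @param methods Methods passed to [run_method()].
#' @param n_images_choices Replicate image counts sampled per plant.
#' @param scene A [scene_config()] template (its seed is overridden per
#'   acquisition).
#' @param min_pixels Pixel-count exclusion threshold; default scales the
#'   full-frame rule (5000 px of 128,000) to the scene area.
#' @param reps Monte Carlo CV replicates for LV selection.
#' @param snv Apply SNV to the plant-level mean spectra (default TRUE).
#' @param library Endmember library driving the forward model (default
#'   [endmember_library()]).
#' @param seeds List with `sim`, `split`, `cv` integer seeds.
#' @export
study_config <- function(n_plants = 185L, n_tissue_plants = 15L,
                         attributes = c("nitrogen", "sugars"),
                         dataset = c("BL+PS", "BL"),
                         range_nm = NULL,
                         methods = "PLSR-AW",
                         n_images_choices = c(2L, 3L),
                         scene = scene_config(lines = 80L, samples = 64L),
                         min_pixels = NULL,
                         reps = 20L,
                         snv = TRUE,
                         library = endmember_library(),
                         seeds = list(sim = 11L, split = 12L, cv = 13L)) {
  dataset <- match.arg(dataset)
  if (is.null(min_pixels)) {
    min_pixels <- 5000 * (scene$lines * scene$samples) / (400 * 320)
  }
  specs <- default_attribute_specs()
  missing <- setdiff(attributes, names(specs))
  if (length(missing) > 0) {
    stop("no attribute spec for: ", paste(missing, collapse = ", "))
  }
  structure(list(n_plants = as.integer(n_plants),
                 n_tissue_plants = as.integer(n_tissue_plants),
                 attributes = attributes, dataset = dataset,
                 range_nm = range_nm, methods = methods,
                 n_images_choices = as.integer(n_images_choices),
                 scene = scene, min_pixels = min_pixels, reps = reps,
                 snv = snv, library = library,
                 seeds = seeds, specs = specs),
            class = "study_config")
}

#' Simulate a study's acquisitions and extract plant spectra
#'
#' Draws the attribute table, then for every sample unit (one blade
#' acquisition per plant; additionally one pseudostem acquisition for the
#' tissue subset) generates 2-3 replicate raw cubes, calibrates each with
#' its white/dark references, segments the plant, extracts the ROI mean
#' spectrum and averages replicates. Plant size (hence ROI pixel count) is
#' tied to the plant's visual-yield attribute, so pixel count is an
#' informative predictor of yield. Units failing the pixel-count rule are
#' flagged excluded.
#'
#' @param config A [study_config()].
#' @param progress Print a dot per plant (default FALSE).
#' @return List: `table` (attribute table), `units` (data.frame of
#'   plant_id, tissue, n_images, n_pixels_mean, excluded), `X` (matrix of
#'   raw mean reflectance spectra, one row per non-excluded unit),
#'   `wavelengths`, `library`, `config`.
#' @export
simulate_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  lib <- config$library
  table <- generate_attribute_table(config$specs, config$n_plants,
                                    seed = config$seeds$sim)
  plants <- unique(table$plant_id)
  vy_spec <- config$specs$visual_yield

  # sample units: BL for every plant, PS for the tissue subset
  units <- data.frame(
    plant_id = c(plants, plants[seq_len(config$n_tissue_plants)]),
    tissue = c(rep("BL", length(plants)), rep("PS", config$n_tissue_plants)),
    stringsAsFactors = FALSE
  )

  set.seed(config$seeds$sim + 500009L)
  n_images <- sample(config$n_images_choices, nrow(units), replace = TRUE)
  unit_seed <- sample.int(2^31 - 1, nrow(units))

  spectra <- vector("list", nrow(units))
  npix <- numeric(nrow(units)); excl <- logical(nrow(units))
  for (u in seq_len(nrow(units))) {
    row <- table[table$plant_id == units$plant_id[u] &
                   table$tissue == units$tissue[u], ]
    vy <- row$visual_yield
    frac <- 0.2 + 0.45 * clip((vy - vy_spec$min) / (vy_spec$max - vy_spec$min), 0, 1)
    reps <- lapply(seq_len(n_images[u]), function(r) {
      sc <- config$scene
      sc$plant_fraction <- frac
      sc$seed <- (unit_seed[u] + r) %% (2^31 - 1)
      sim <- generate_cube(as.list(row), lib, sc, tissue = units$tissue[u])
      refl <- calibrate(sim$raw, sim$refs)
      mean_spectrum(refl, segment(refl))
    })
    agg <- aggregate_plant(reps, min_pixels = config$min_pixels,
                           plant_id = units$plant_id[u],
                           tissue = units$tissue[u])
    spectra[[u]] <- agg$spectrum
    npix[u] <- agg$n_pixels_mean
    excl[u] <- agg$excluded
    if (progress && units$tissue[u] == "BL") cat(".")
  }
  if (progress) cat("\n")
  units$n_images <- n_images
  units$n_pixels_mean <- npix
  units$excluded <- excl

  X <- do.call(rbind, spectra)
  list(table = table, units = units, X = X, wavelengths = lib$wavelengths,
       library = lib, config = config)
}

# rows of the study belonging to one dataset variant, with the response
assemble_dataset <- function(study, attribute, dataset = study$config$dataset) {
  units <- study$units
  keep <- !units$excluded & if (dataset == "BL") units$tissue == "BL" else TRUE
  y <- mapply(function(pid, tis) {
    study$table[study$table$plant_id == pid & study$table$tissue == tis, attribute]
  }, units$plant_id, units$tissue)
  keep <- keep & !is.na(y)
  list(X = study$X[keep, , drop = FALSE], y = as.numeric(y[keep]),
       plant_ids = units$plant_id[keep], tissue = units$tissue[keep],
       n_pixels = units$n_pixels_mean[keep])
}

#' Run the full study
#'
#' Simulates (or reuses) the study, then for every attribute and method:
#' restricts the wavelength range if configured, applies SNV, splits plants
#' 2/3 calibration / 1/3 validation, selects LVs by Monte Carlo CV +
#' Adjusted Wold, fits, and reports calibration/validation statistics in
#' the standard report shape. Deterministic given the config seeds.
#'
#' @param config A [study_config()].
#' @param study Optional pre-simulated output of [simulate_study()] (must
#'   match the config).
#' @param out_dir Optional directory; writes `report.csv`, the attribute
#'   table, and a provenance log.
#' @return List: `report` (data.frame, one row per attribute x method),
#'   `models` (per attribute: the fitted PLSR model of the first PLSR
#'   method, with its pipeline record), `split`, `study`.
#' @export
run_study <- function(config, study = NULL, out_dir = NULL) {
  if (is.null(study)) study <- simulate_study(config)
  rows <- list(); models <- list()
  for (attribute in config$attributes) {
    ds <- assemble_dataset(study, attribute, dataset = config$dataset)
    pipeline <- list(snv = config$snv, range_nm = config$range_nm)
    Xp <- preprocess_matrix(ds$X, study$wavelengths, pipeline)
    split <- split_calibration_validation(ds$plant_ids, seed = config$seeds$split)
    in_cal <- ds$plant_ids %in% split$calibration
    X_cal <- Xp[in_cal, , drop = FALSE]; y_cal <- ds$y[in_cal]
    X_val <- Xp[!in_cal, , drop = FALSE]; y_val <- ds$y[!in_cal]
    for (method in config$methods) {
      rep_row <- run_method(method, X_cal, y_cal, X_val, y_val,
                            seed = config$seeds$cv, reps = config$reps)
      rep_row <- cbind(data.frame(attribute = attribute,
                                  dataset = config$dataset,
                                  stringsAsFactors = FALSE), rep_row)
      rows[[length(rows) + 1]] <- rep_row
      if (grepl("^PLSR", method) && is.null(models[[attribute]])) {
        fit <- fit_plsr(X_cal, y_cal, n_lv = max(1L, rep_row$lv))
        models[[attribute]] <- list(model = fit, pipeline = pipeline,
                                    lv = rep_row$lv)
      }
    }
  }
  report <- do.call(rbind, rows)
  split <- split_calibration_validation(unique(study$units$plant_id),
                                        seed = config$seeds$split)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    write_attribute_table(study$table, file.path(out_dir, "attribute_table.csv"))
    log <- c(paste0("n_plants=", config$n_plants),
             paste0("dataset=", config$dataset),
             paste0("scene=", config$scene$lines, "x", config$scene$samples,
                    "x", config$scene$bands),
             paste0("noise_sd=", config$scene$noise_sd),
             paste0("lighting_gradient=", config$scene$lighting_gradient),
             paste0("min_pixels=", config$min_pixels),
             paste0("seed_sim=", config$seeds$sim),
             paste0("seed_split=", config$seeds$split),
             paste0("seed_cv=", config$seeds$cv))
    writeLines(log, file.path(out_dir, "provenance.log"))
  }
  list(report = report, models = models, split = split, study = study)
}

#' Visual-yield model with pixel count as an extra predictor
#'
#' Yield tracks plant size, which the spectra alone cannot see; the ROI
#' pixel count can. Fits PLSR on SNV spectra augmented with a standardized
#' pixel-count column and reports it against the spectrum-only model. A
#' constant pixel-count column carries no information and is dropped, in
#' which case the two models coincide.
#'
#' @param config A [study_config()] (attribute fixed to `visual_yield`).
#' @param study Optional pre-simulated study.
#' @return List: `report` (two rows: augmented and spectra-only), each a
#'   [model_report()]-shaped row with a `predictors` provenance flag.
#' @export
run_visual_yield <- function(config, study = NULL) {
  if (is.null(study)) study <- simulate_study(config)
  ds <- assemble_dataset(study, "visual_yield")
  Xp <- preprocess_matrix(ds$X, study$wavelengths, list(snv = TRUE))
  split <- split_calibration_validation(ds$plant_ids, seed = config$seeds$split)
  in_cal <- ds$plant_ids %in% split$calibration

  fit_one <- function(X, predictors) {
    X_cal <- X[in_cal, , drop = FALSE]; y_cal <- ds$y[in_cal]
    X_val <- X[!in_cal, , drop = FALSE]; y_val <- ds$y[!in_cal]
    curve <- mc_cv_curve(X_cal, y_cal, lv_max = min(20L, nrow(X_cal) - 12L),
                         folds = 10L, reps = config$reps,
                         seed = config$seeds$cv)
    a <- adjusted_wold(curve)
    fit <- fit_plsr(X_cal, y_cal, n_lv = a)
    out <- model_report(y_val, predict(fit, X_val), subset = "validation",
                        lv = fit$n_lv)
    out$predictors <- predictors
    out
  }

  px <- ds$n_pixels
  if (stats::sd(px[in_cal]) > 0) {
    pxs <- (px - mean(px[in_cal])) / stats::sd(px[in_cal])
    X_aug <- cbind(Xp, pixel_count = pxs)
    aug_flag <- "spectra+pixel_count"
  } else {
    X_aug <- Xp
    aug_flag <- "spectra (constant pixel count dropped)"
  }
  report <- rbind(fit_one(X_aug, aug_flag), fit_one(Xp, "spectra"))
  list(report = report, split = split)
}
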