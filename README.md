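# grasshsi

Chemometrics for predicting the forage quality of perennial ryegrass
(*Lolium perenne*) from line-scan hyperspectral images.

Forage composition — sugars, nitrogen/crude protein, fibre, digestibility,
energy — drives animal performance in pasture-based systems, but measuring
it requires destructive harvest and wet chemistry. Hyperspectral imaging
(HSI) offers a non-invasive alternative: a line-scan camera records a full
reflectance spectrum (here 235 bands, 550–1700 nm) at every pixel of a
plant image, and regression models calibrated against wet chemistry
predict the attributes from the spectra. `grasshsi` implements that whole
pipeline for plant breeders and spectroscopists:

* **ENVI I/O and calibration** — reads/writes ENVI cubes (BIL/BIP/BSQ) and
  converts raw irradiance to reflectance with white/dark references,
  `R = (I − D)/(W − D)`.
* **Segmentation and plant spectra** — plant pixels are `R ≥ 0.3` at
  1080 nm; mean ROI spectra are averaged over 2–3 replicate images, with a
  pixel-count exclusion rule for failed acquisitions.
* **Preprocessing** — standard normal variate (SNV), wavelength-range
  restriction, band subsampling.
* **PLS regression (NIPALS)** — with Monte Carlo 10-fold cross-validation
  and Adjusted Wold latent-variable selection (thresholds 1 and 0.99):
  stop at the first k with press(k+1)/press(k) ≥ θ.
* **Wavelength selection** — CARS (competitive adaptive reweighted
  sampling) and VIP (variable importance in projection,
  `mean(VIP²) = 1`), plus an eleven-method comparison harness
  (PLSR variants, GPR, SVM, RF, MLR, stepwise, lasso, robust MLR).
* **Per-pixel trait maps** — plant-level calibrations applied per pixel
  (SNV per pixel, hence invariant to lighting gradients), with 558/740/937
  nm false-colour rendering.
* **Pseudostem vs blade analyses** — paired tissue contrasts (BL − PS),
  tissue regressions, sugar partitioning ratios, crude protein (N × 6.25),
  and canonical-variate tissue classification on every-2nd-wavelength
  spectra.
* **A synthetic scene generator** — attribute tables with published
  population summaries and pseudostem/blade coupling, plus a Beer–Lambert
  forward model from concentrations to cubes (with white/dark references
  and ground-truth masks), so the full pipeline runs and is tested without
  any plant data.

See `vignettes/grasshsi-methods.Rmd` for the models, assumptions and
design choices, and `analysis/01_simulate.R` … `analysis/06_trait_maps.R`
for the study-scale drivers (each writes its tables under `results/`).

## Worked example

Simulate a 40-plant study (8 plants with separate pseudostem/blade
acquisitions), image every plant 2–3 times on a 60×48-pixel frame,
extract ROI mean spectra, and fit SNV + PLSR with Monte-Carlo-CV Adjusted
Wold selection:

```r
library(grasshsi)

cfg <- study_config(n_plants = 40, n_tissue_plants = 8,
                    attributes = c("nitrogen", "sugars"),
                    scene = scene_config(lines = 60, samples = 48),
                    reps = 10)
study <- simulate_study(cfg)
res <- run_study(cfg, study = study)
res$report[, c("attribute", "lv", "r2_cal", "rmse_cal", "n_cal",
               "r2_val", "rmse_val", "n_val")]
#>   attribute lv r2_cal rmse_cal n_cal r2_val rmse_val n_val
#> 1  nitrogen  5  0.996    0.041    33  0.993   0.0838    15
#> 2    sugars 15  1.000    0.160    33  1.000   0.8980    15
```

Reading the rows: for nitrogen the Wold criterion settled on 5 latent
variables; calibration used 33 sample units (blade acquisitions of the
calibration plants plus the pseudostem acquisitions of calibration plants
in the tissue subset) and validation the held-out 15; R² is the squared
observed–predicted correlation and RMSE is in the attribute's units (% for
nitrogen, mg/g for sugars). Validation R² near 1 is expected here — the
synthetic forward model is noiseless apart from sensor noise, so this is a
parameter-recovery check, not a field-accuracy claim.

A per-pixel nitrogen map of a two-zone plant (pseudostem base, blade top)
then reproduces the within-plant pattern — higher nitrogen in the blades,
higher sugars in the pseudostems:

```r
tab <- study$table
ps <- as.list(tab[tab$plant_id == "plant_001" & tab$tissue == "PS", ])
bl <- as.list(tab[tab$plant_id == "plant_001" & tab$tissue == "BL", ])
sim <- generate_two_zone_cube(ps, bl, study$library, cfg$scene)
map <- predict_map(calibrate(sim$raw, sim$refs), res$models$nitrogen$model,
                   pipeline = res$models$nitrogen$pipeline)
```

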