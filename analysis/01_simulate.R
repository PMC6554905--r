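#!/usr/bin/env Rscript
# Stage 1 -- simulate the study population.
#
# Draws the 185-plant attribute table (13 forage-quality attributes, with
# pseudostem/blade structure for a 15-plant subset), images every sample
# unit with 2-3 replicate acquisitions, and extracts the plant-level mean
# reflectance spectra. Writes the attribute table, the spectra matrix and
# one example ENVI scene so later stages (and outside tools) can inspect
# the raw data.

source("analysis/00_config.R")

cfg <- base_config()
study <- load_study(cfg)

write_attribute_table(study$table, file.path(RESULTS_DIR, "attribute_table.csv"))

# spectra table: plant, tissue, pixel stats, then one column per band
spectra <- cbind(study$units,
                 setNames(as.data.frame(study$X),
                          paste0("nm", round(study$wavelengths, 1))))
write.csv(spectra, file.path(RESULTS_DIR, "plant_spectra.csv"), row.names = FALSE)

# one example acquisition, exported as ENVI + references + truth mask
row <- as.list(study$table[study$table$plant_id == "plant_001" &
                             study$table$tissue == "BL", ])
sc <- cfg$scene; sc$seed <- 1001L
sim <- generate_cube(row, study$library, sc)
write_simulated_scene(sim, file.path(RESULTS_DIR, "example_scene"), "plant_001_bl")

excl <- sum(study$units$excluded)
cat("simulated", nrow(study$units), "sample units (",
    sum(study$units$tissue == "BL"), "blade +",
    sum(study$units$tissue == "PS"), "pseudostem );",
    excl, "excluded by the pixel-count rule\n")
cat("mean ROI pixel count:", round(mean(study$units$n_pixels_mean)), "\n")
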