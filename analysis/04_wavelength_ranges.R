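#!/usr/bin/env Rscript
# Stage 4 -- restricted wavelength ranges and key-wavelength selection.
#
# Refits the nitrogen and total-sugar models on the VNIR-only (550-900 nm)
# and extended-NIR-only (900-1700 nm) band sets (SNV recomputed on each
# restricted set), and reports the VIP >= 1 key-wavelength ranges of the
# full-spectrum models.

source("analysis/00_config.R")

ranges <- list(full = NULL, vnir = c(550, 900), enir = c(900, 1700))
rows <- list()
for (rn in names(ranges)) {
  cfg <- base_config(attributes = c("nitrogen", "sugars"),
                     range_nm = ranges[[rn]])
  study <- load_study(cfg)
  res <- run_study(cfg, study = study)
  rep <- res$report
  rep$range <- if (is.null(ranges[[rn]])) "550-1700" else
    paste(ranges[[rn]], collapse = "-")
  rows[[rn]] <- rep
}
report <- do.call(rbind, rows)
write.csv(report, file.path(RESULTS_DIR, "wavelength_range_models.csv"),
          row.names = FALSE)
cat("restricted-range model performance:\n")
print(report[, c("attribute", "range", "lv", "r2_cal", "r2_val",
                 "rmse_val", "intercept", "slope", "bias")],
      digits = 3, row.names = FALSE)

# key wavelengths from the full-spectrum models, VIP >= 1
cfg <- base_config(attributes = c("nitrogen", "sugars"))
study <- load_study(cfg)
res <- run_study(cfg, study = study)
wl <- study$wavelengths
for (att in c("nitrogen", "sugars")) {
  sel <- vip_select(res$models[[att]]$model, 1.0)
  bands <- band_ranges_nm(sel, wl)
  cat("\nkey wavelength ranges for", att, "(VIP >= 1):\n")
  print(bands, row.names = FALSE)
  write.csv(bands, file.path(RESULTS_DIR, paste0("key_wavelengths_", att, ".csv")),
            row.names = FALSE)
}
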