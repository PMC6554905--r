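#!/usr/bin/env Rscript
# Stage 3 -- eleven-method comparison for nitrogen (BL+PS).
#
# Benchmarks the PLSR variants (Adjusted Wold at thresholds 1 and 0.99,
# CARS and VIP wavelength selection) against Gaussian process regression,
# SVM, random forest, MLR, stepwise MLR, lasso and robust MLR on the same
# SNV spectra and the same calibration/validation split.

source("analysis/00_config.R")

methods <- c("PLSR-AW", "PLSR-AW0.99", "PLSR-CARS", "PLSR-VIP",
             "GPR", "SVM", "RF", "MLR", "SMLR", "LASSO", "RMLR")
cfg <- base_config(attributes = "nitrogen", methods = methods)
study <- load_study(cfg)
res <- run_study(cfg, study = study)

write.csv(res$report, file.path(RESULTS_DIR, "method_comparison_nitrogen.csv"),
          row.names = FALSE)
cat("nitrogen (BL+PS), one row per method:\n")
print(res$report[, c("method", "lv", "n_bands", "r2_cal", "rmse_cal",
                     "r2_val", "rmse_val")], digits = 3, row.names = FALSE)
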