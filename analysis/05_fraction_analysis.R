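#!/usr/bin/env Rscript
# Stage 5 -- pseudostem versus blade composition.
#
# Paired tissue contrasts for the attributes with tissue-resolved values,
# the blade~pseudostem regressions, the LMW-vs-HMW partitioning ratio,
# crude protein conversion, and canonical-variate classification of tissue
# type from the every-2nd-wavelength SNV spectra.

source("analysis/00_config.R")

cfg <- base_config()
study <- load_study(cfg)
tab <- study$table
subset_ids <- unique(tab$plant_id)[seq_len(cfg$n_tissue_plants)]

contrast_rows <- list(); regression_rows <- list()
for (att in c("nitrogen", "sugars", "lmw", "hmw")) {
  ps <- tab[[att]][tab$tissue == "PS" & tab$plant_id %in% subset_ids]
  bl <- tab[[att]][tab$tissue == "BL" & tab$plant_id %in% subset_ids]
  ct <- tissue_contrast(ps, bl, att)
  contrast_rows[[att]] <- data.frame(
    attribute = att, n = ct$n, mean_ps = ct$mean_ps, sd_ps = ct$sd_ps,
    mean_bl = ct$mean_bl, sd_bl = ct$sd_bl, diff_bl_minus_ps = ct$diff,
    se_diff = ct$se_diff, p_value = ct$p_value)
  fit <- ps_bl_regression(ps, bl)
  regression_rows[[att]] <- data.frame(
    attribute = att, slope = fit$slope, slope_se = fit$slope_se,
    r2 = fit$r2, rmse = fit$rmse, n = fit$n)
}
contrasts <- do.call(rbind, contrast_rows)
regressions <- do.call(rbind, regression_rows)
write.csv(contrasts, file.path(RESULTS_DIR, "tissue_contrasts.csv"),
          row.names = FALSE)
write.csv(regressions, file.path(RESULTS_DIR, "ps_bl_regressions.csv"),
          row.names = FALSE)
cat("tissue contrasts (BL - PS):\n")
print(contrasts, digits = 3, row.names = FALSE)
cat("\nblade~pseudostem regressions:\n")
print(regressions, digits = 3, row.names = FALSE)

part <- relative_partitioning(
  lmw_ps = contrasts$mean_ps[contrasts$attribute == "lmw"],
  lmw_bl = contrasts$mean_bl[contrasts$attribute == "lmw"],
  hmw_ps = contrasts$mean_ps[contrasts$attribute == "hmw"],
  hmw_bl = contrasts$mean_bl[contrasts$attribute == "hmw"])
cat("\nLMW vs HMW blade/pseudostem partitioning ratio:", round(part, 2), "\n")
mean_n <- contrasts$mean_bl[contrasts$attribute == "nitrogen"]
cat("crude protein at the blade nitrogen mean:",
    round(crude_protein(mean_n), 1), "%\n")

# tissue classification from spectra (every 2nd wavelength)
units <- study$units
sub <- units$plant_id %in% subset_ids & !units$excluded
X <- t(apply(study$X[sub, , drop = FALSE], 1, snv))
labels <- units$tissue[sub]
proj <- tissue_cva(X, labels, stride = 2)
scores <- data.frame(plant_id = units$plant_id[sub], tissue = labels,
                     cv1 = proj$scores[, 1], cv2 = proj$scores[, 2])
write.csv(scores, file.path(RESULTS_DIR, "cva_scores.csv"), row.names = FALSE)
ps1 <- scores$cv1[scores$tissue == "PS"]; bl1 <- scores$cv1[scores$tissue == "BL"]
cat("\nCVA: Wilks lambda =", signif(proj$wilks_lambda, 3),
    "| CV1 separates tissues:",
    if (max(ps1) < min(bl1) || max(bl1) < min(ps1)) "no overlap" else "overlap",
    "\n")
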