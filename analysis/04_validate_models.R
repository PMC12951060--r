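#!/usr/bin/env Rscript
# Step 4 — discrimination and calibration of the selected models.
#
# Refits each stratum's selected model, reports the apparent AUC, the
# Hosmer-Lemeshow calibration test, and a 2000-resample bootstrap
# internal validation; writes the ROC and calibration curves as CSV.

suppressPackageStartupMessages(library(pulseharmonics))

seed <- 1L
out_dir <- "results"
features <- read_feature_table(file.path(out_dir, "features.csv"))
features$label <- as.logical(features$label)

for (sx in c("male", "female")) {
  df <- features[features$sex == sx, ]
  labels <- as.numeric(df$label)
  stored <- read_model_json(file.path(out_dir, sprintf("model_%s.json", sx)))
  vars <- unlist(stored$selected)
  fit <- fit_logistic(df[, vars, drop = FALSE], labels)

  val <- validate_model(fit, df, labels, n_resamples = 2000L,
                        seed = seed + match(sx, c("male", "female")))
  cat(sprintf("\n[%s] apparent AUC %.3f | HL %.2f on %d df (P = %.2f)\n",
              sx, val$auc, val$hl_statistic, val$hl_df, val$hl_p))
  cat(sprintf("  bootstrap (%d resamples): mean AUC %.3f, 95%% CI [%.3f, %.3f]\n",
              val$n_resamples, val$bootstrap_mean_auc,
              val$bootstrap_ci[1], val$bootstrap_ci[2]))

  utils::write.csv(val$roc_points,
                   file.path(out_dir, sprintf("roc_%s.csv", sx)),
                   row.names = FALSE)
  utils::write.csv(val$calibration_points,
                   file.path(out_dir, sprintf("calibration_%s.csv", sx)),
                   row.names = FALSE)
  write_model_json(val, file.path(out_dir, sprintf("validation_%s.json", sx)))
}
cat("\nwrote results/roc_*.csv, calibration_*.csv, validation_*.json\n")
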