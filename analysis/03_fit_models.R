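#!/usr/bin/env Rscript
# Step 3 — sex-stratified AIC model selection.
#
# For each sex stratum, runs forward, backward and stepwise AIC searches
# over the signed and absolute harmonic difference features, keeps the
# minimum-AIC model, and writes the coefficient tables
# (Coefficient / SE / tStat / P Value).

suppressPackageStartupMessages(library(pulseharmonics))

out_dir <- "results"
features <- read_feature_table(file.path(out_dir, "features.csv"))
features$label <- as.logical(features$label)

for (sx in c("male", "female")) {
  df <- features[features$sex == sx, ]
  labels <- as.numeric(df$label)
  cands <- prepare_candidates(
    df[, grep("^(absd|d)[CPD]\\d+(CV)?$", names(df), value = TRUE)])
  ep <- suppressWarnings(epv_check(sum(labels), ncol(cands)))
  cat(sprintf("\n[%s] n = %d, events = %d, candidates = %d\n",
              sx, nrow(df), sum(labels), ncol(cands)))
  if (!ep$ok) cat("  ", ep$message, "\n")

  searches <- suppressWarnings(run_searches(cands, labels))
  for (m in names(searches))
    cat(sprintf("  %-8s AIC %.2f with %d variables\n", m,
                searches[[m]]$model$aic, length(searches[[m]]$selected)))
  best <- select_best(searches)
  cat(sprintf("  best: %s (AIC %.2f): %s\n", best$method, best$model$aic,
              paste(best$selected, collapse = ", ")))

  tab <- coef_table(best$model, digits = 2)
  print(tab, row.names = FALSE)
  utils::write.csv(tab, file.path(out_dir, sprintf("coefficients_%s.csv", sx)),
                   row.names = FALSE)
  write_model_json(list(sex = sx, method = best$method,
                        selected = best$selected, model = best$model),
                   file.path(out_dir, sprintf("model_%s.json", sx)))
}
cat("\nwrote results/coefficients_{male,female}.csv and model JSONs\n")
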