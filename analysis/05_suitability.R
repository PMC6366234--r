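# The random-forest uplift suitability model under the three predictor
# frameworks, and the range-masked, TSS-binarized suitability map from the
# static model.

source("analysis/00_config.R")

seg <- load_cache("seg")
flaps <- load_cache("flaps")
stack <- load_cache("stack")
landscape <- load_cache("landscape")

ens <- list()
for (fw in c("static", "dynamic", "combined")) {
  obs <- assemble_observations(seg$events, flaps, stack, fw)
  ens[[fw]] <- fit_rf_cv(obs, seed = SEED)
  m <- ens[[fw]]$metrics
  cat(sprintf("%-8s AUC test %.2f +/- %.2f (train %.2f), sens %.2f, spec %.2f, threshold %.2f\n",
              fw, mean(m$auc_test), sd(m$auc_test), mean(m$auc_train),
              mean(m$sensitivity), mean(m$specificity), ens[[fw]]$threshold))
}

imp <- sort(ens$static$importance[, 1], decreasing = TRUE)
cat("Static-model importance (accuracy decrease), top 5:\n")
print(round(head(imp, 5), 1))

map <- predict_map(ens$static, stack)
suit <- map$binary$values
cat(sprintf("Suitability map: %.1f%% suitable, %.1f%% unsuitable, %.1f%% unclassified\n",
            100 * mean(suit == 1, na.rm = TRUE),
            100 * mean(suit == 0, na.rm = TRUE), 100 * mean(is.na(suit))))
cat(sprintf("Planted field: %.1f%% of cells above p = 0.5\n",
            100 * mean(landscape$p_uplift$values > 0.5)))

write_ascii_grid(map$probability,
                 file.path(RESULTS, "suitability_probability.asc"))
write_ascii_grid(map$binary, file.path(RESULTS, "suitability_binary.asc"))
metrics <- do.call(rbind, lapply(names(ens), function(fw)
  cbind(framework = fw, ens[[fw]]$metrics)))
write.csv(metrics, file.path(RESULTS, "suitability_metrics.csv"),
          row.names = FALSE)
saveRDS(ens, cache_path("rf"))
saveRDS(map, cache_path("suitability_map"))
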