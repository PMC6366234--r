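# The static energy landscape: daily mean ODBA against daily mean predicted
# uplift suitability along each bird's route, with individual random
# intercepts.

source("analysis/00_config.R")

acc <- load_cache("acc")
map <- load_cache("suitability_map")

records <- build_daily_records(acc, map)
cat(sprintf("Daily records: %d individual-days from %d individuals\n",
            nrow(records), length(unique(records$individual))))

fit <- fit_energy_model(records)
cat(sprintf("sqrt(daily ODBA) ~ daily suitability: slope %.3f +/- %.3f\n",
            fit$slope, fit$slope_se))
cat(sprintf("AIC %.2f vs null %.2f (delta %.2f): %s\n",
            fit$aic, fit$null_aic, fit$delta_aic,
            if (fit$delta_aic < -2) "the suitability map carries energetic information"
            else "no support for the suitability term"))
if (fit$slope < 0)
  cat("Birds spent more energy on days spent over landscapes the map rates poorly for uplift.\n")

write.csv(records, file.path(RESULTS, "daily_records.csv"), row.names = FALSE)
summ <- fit[c("slope", "slope_se", "ranef_sd", "aic", "null_aic",
              "delta_aic", "n_obs", "n_individuals")]
jsonlite::write_json(summ, file.path(RESULTS, "energy_model.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
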