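# ODBA from the accelerometer bursts, k-means activity classes, burst
# geolocation, and high-altitude flapping as uplift absences.

source("analysis/00_config.R")

sim <- load_cache("sim")
stack <- load_cache("stack")

acc <- compute_odba(sim$acc)
acc <- classify_activity(acc, seed = SEED)
acc <- geolocate_bursts(acc, sim$gps, stack$layers$dem)
flaps <- select_flapping(acc)

cat(sprintf("ACC bursts: %d; activity classes: %s\n", nrow(acc),
            paste(sprintf("%s %d", levels(acc$activity_class),
                          table(acc$activity_class)), collapse = ", ")))
cat(sprintf("Flapping fraction of classified flight bursts: %.3f\n",
            mean(acc$behaviour == "flapping")))
cat(sprintf("Most-active recovery of simulated flapping: %.2f\n",
            mean(acc$activity_class[acc$behaviour == "flapping"] == "most")))
cat(sprintf("Uplift absences (most active, > 100 m above ground): %d\n",
            nrow(flaps)))

write.csv(acc[, setdiff(names(acc), "samples")],
          file.path(RESULTS, "acc_classified.csv"), row.names = FALSE)
write.csv(flaps, file.path(RESULTS, "flapping_absences.csv"),
          row.names = FALSE)
saveRDS(acc, cache_path("acc"))
saveRDS(flaps, cache_path("flaps"))
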