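# Simulate the study system: a landscape with a known uplift field, and a
# season of stork GPS/ACC tracking over it on the loggers' duty cycle.

source("analysis/00_config.R")

landscape <- generate_landscape(SEED, shape = SHAPE)
cat(sprintf("Landscape: %d x %d cells at %g m; mean uplift probability %.2f, %.0f%% of cells above 0.5\n",
            SHAPE[1], SHAPE[2], landscape$config$res,
            mean(landscape$p_uplift$values),
            100 * mean(landscape$p_uplift$values > 0.5)))

sim <- simulate_tracks(landscape, n_birds = N_BIRDS, seed = SEED + 1)
fixmix <- prop.table(table(sim$gps$behaviour))
cat(sprintf("Tracks: %d birds, %d GPS fixes, %d ACC bursts\n",
            N_BIRDS, nrow(sim$gps), nrow(sim$acc)))
cat(sprintf("True fix-level mix: %s\n",
            paste(sprintf("%s %.2f", names(fixmix), fixmix), collapse = ", ")))

write_landscape(landscape, file.path(RESULTS, "landscape"))
write_movebank_gps(sim$gps, file.path(RESULTS, "gps.csv"))
write_movebank_acc(sim$acc, file.path(RESULTS, "acc.csv"))
write.csv(sim$attempts, file.path(RESULTS, "truth_attempts.csv"),
          row.names = FALSE)
saveRDS(landscape, cache_path("landscape"))
saveRDS(sim, cache_path("sim"))
cat("Wrote landscape rasters, Movebank-dialect CSVs and the truth record.\n")
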