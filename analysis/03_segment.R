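# Segment the 1 Hz GPS bursts into circular soaring, linear soaring and
# gliding; extract soaring events as uplift presences.

source("analysis/00_config.R")

sim <- load_cache("sim")
seg <- segment_tracks(sim$gps)

tb <- time_budget(seg$segments)
cat(sprintf("Classified %d segments (%.1f h of burst flight)\n",
            nrow(seg$segments), sum(seg$segments$duration) / 3600))
cat(sprintf("Time budget: soaring %.2f (circular %.2f + linear %.2f), gliding %.2f\n",
            tb[["soaring"]], tb[["circular_soaring"]],
            tb[["linear_soaring"]], tb[["gliding"]]))
cat(sprintf("Agreement with simulated truth: %.1f%%\n",
            100 * mean(seg$segments$behaviour == seg$segments$behaviour_true)))
cat(sprintf("Soaring events (uplift presences): %d\n", nrow(seg$events)))

write.csv(seg$segments, file.path(RESULTS, "segments.csv"), row.names = FALSE)
write.csv(seg$events, file.path(RESULTS, "soaring_events.csv"),
          row.names = FALSE)
saveRDS(seg, cache_path("seg"))
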