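# Shared configuration for the analysis scripts. Each numbered script can be
# run in order from the repository root:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_terrain.R
#   ...
# Intermediate objects are cached under results/cache/, final tables and
# rasters under results/.

library(upliftscape)

SEED <- 42
N_BIRDS <- 20
SHAPE <- c(150, 150)

RESULTS <- "results"
CACHE <- file.path(RESULTS, "cache")
dir.create(CACHE, recursive = TRUE, showWarnings = FALSE)

cache_path <- function(name) file.path(CACHE, paste0(name, ".rds"))
load_cache <- function(name) {
  p <- cache_path(name)
  if (!file.exists(p))
    stop("missing ", p, ": run the earlier analysis scripts first",
         call. = FALSE)
  readRDS(p)
}
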