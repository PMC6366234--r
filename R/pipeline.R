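# End-to-end pipeline: landscape -> tracks -> terrain -> segmentation ->
# accelerometry -> suitability -> intensity -> energy.

#' Assemble the full predictor stack of a landscape
#'
#' Derives the terrain layers from the landscape DEM and co-registers them
#' with NDVI, land use, urban footprint, latitude and the dynamic uplift
#' potentials.
#'
#' @param landscape a `uls_landscape`.
#' @return a `uls_stack`.
#' @export
landscape_stack <- function(landscape) {
  terr <- derive_terrain(landscape$dem)
  uls_stack(c(terr$layers,
              list(ndvi = landscape$ndvi,
                   land_use = landscape$land_use,
                   urban_footprint = landscape$urban_footprint,
                   latitude = landscape$latitude,
                   thermal_uplift = landscape$thermal_uplift,
                   orographic_uplift = landscape$orographic_uplift)))
}

#' Run the full uplift-landscape analysis on synthetic data
#'
#' One seeded command covering every stage: simulate a landscape and stork
#' tracks, derive the terrain predictor stack, segment the GPS bursts into
#' flight behaviours and extract soaring events (presences), process the
#' accelerometer bursts into flapping absences, fit the random-forest
#' suitability model and predict the range-masked binary map, fit the GAM
#' intensity model and predict intensity on suitable cells, and fit the
#' daily energy mixed model. When `out_dir` is given, all tables are written
#' as CSV, all rasters as ESRI ASCII grids, and all fit summaries as JSON.
#'
#' @param seed master seed for every stochastic stage.
#' @param n_birds number of simulated individuals.
#' @param shape landscape grid dimensions.
#' @param out_dir optional output directory.
#' @param landscape_cfg,schedule_cfg,flight_cfg stage configurations.
#' @param frameworks frameworks to fit in the suitability and intensity
#'   stages (the first is used for the maps).
#' @param quiet suppress progress messages.
#' @return list with all intermediate and final objects: `landscape`,
#'   `sim`, `stack`, `collinearity`, `segments`, `events`, `acc`, `flaps`,
#'   `observations`, `rf`, `suitability`, `cells`, `gams`, `gam_ranking`,
#'   `intensity_map`, `daily_records`, `energy`.
#' @export
run_pipeline <- function(seed = 1, n_birds = 20, shape = c(150, 150),
                         out_dir = NULL,
                         landscape_cfg = landscape_config(),
                         schedule_cfg = schedule_config(),
                         flight_cfg = flight_config(),
                         frameworks = c("static", "dynamic", "combined"),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)

  say("1/7 landscape")
  landscape <- generate_landscape(seed, shape, landscape_cfg)
  say("2/7 tracks (", n_birds, " birds)")
  sim <- simulate_tracks(landscape, n_birds, seed + 1,
                         schedule = schedule_cfg, flight = flight_cfg)
  say("3/7 terrain stack")
  stack <- landscape_stack(landscape)

  say("4/7 GPS segmentation")
  seg <- segment_tracks(sim$gps)
  events <- seg$events

  say("5/7 accelerometry")
  acc <- compute_odba(sim$acc)
  acc <- classify_activity(acc, seed = seed)
  acc <- geolocate_bursts(acc, sim$gps, stack$layers$dem)
  flaps <- select_flapping(acc)

  say("6/7 suitability + intensity (", paste(frameworks, collapse = ", "), ")")
  obs <- lapply(frameworks, function(fw)
    assemble_observations(events, flaps, stack, fw))
  names(obs) <- frameworks
  rf <- lapply(frameworks, function(fw)
    fit_rf_cv(obs[[fw]], seed = seed))
  names(rf) <- frameworks
  suit <- predict_map(rf[[frameworks[1]]], stack)
  coll <- check_multicollinearity(
    stack, obs[[frameworks[1]]][, c("x", "y")])

  cells <- grid_vertical_speeds(sim$gps, stack)
  cells <- filter_percentile(cells)
  gams <- lapply(frameworks, function(fw) fit_intensity_gam(cells, fw))
  names(gams) <- frameworks
  ranking <- compare_frameworks(gams)
  imap <- predict_intensity_map(gams[[frameworks[1]]], stack, suit)

  say("7/7 energy landscape")
  records <- build_daily_records(acc, suit)
  energy <- fit_energy_model(records)

  out <- list(landscape = landscape, sim = sim, stack = stack,
              collinearity = coll,
              segments = seg$segments, embc_fit = seg$embc_fit,
              events = events, acc = acc, flaps = flaps,
              observations = obs, rf = rf, suitability = suit,
              cells = cells, gams = gams, gam_ranking = ranking,
              intensity_map = imap, daily_records = records,
              energy = energy)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Write all pipeline outputs to disk
#'
#' CSV for tables, ESRI ASCII grids for rasters, JSON for fit summaries.
#'
#' @param res result list from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, `out_dir`.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_landscape(res$landscape, file.path(out_dir, "landscape"))
  write_movebank_gps(res$sim$gps, file.path(out_dir, "gps.csv"))
  write_movebank_acc(res$sim$acc, file.path(out_dir, "acc.csv"))
  utils::write.csv(res$sim$attempts, file.path(out_dir, "truth_attempts.csv"),
                   row.names = FALSE)
  utils::write.csv(
    res$sim$gps[, c("individual", "timestamp", "behaviour")],
    file.path(out_dir, "truth_fix_behaviour.csv"), row.names = FALSE)
  utils::write.csv(res$segments, file.path(out_dir, "segments.csv"),
                   row.names = FALSE)
  utils::write.csv(res$events, file.path(out_dir, "soaring_events.csv"),
                   row.names = FALSE)
  utils::write.csv(res$acc[, setdiff(names(res$acc), "samples")],
                   file.path(out_dir, "acc_classified.csv"), row.names = FALSE)
  utils::write.csv(res$flaps, file.path(out_dir, "flapping_absences.csv"),
                   row.names = FALSE)
  utils::write.csv(res$cells, file.path(out_dir, "intensity_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(res$daily_records, file.path(out_dir, "daily_records.csv"),
                   row.names = FALSE)
  write_ascii_grid(res$suitability$probability,
                   file.path(out_dir, "suitability_probability.asc"))
  write_ascii_grid(res$suitability$binary,
                   file.path(out_dir, "suitability_binary.asc"))
  write_ascii_grid(res$intensity_map, file.path(out_dir, "intensity.asc"))

  summ <- list(
    collinearity = res$collinearity,
    rf = lapply(res$rf, function(e) list(
      framework = e$framework, metrics = e$metrics, threshold = e$threshold,
      importance_accuracy = as.list(e$importance[, 1]),
      importance_node_purity = as.list(e$importance[, 2]))),
    gam = lapply(res$gams, function(g) list(
      framework = g$framework, aic = g$aic, adj_r2 = g$adj_r2, n = g$n)),
    gam_ranking = res$gam_ranking,
    energy = res$energy[c("slope", "slope_se", "ranef_sd", "aic", "null_aic",
                          "delta_aic", "n_obs", "n_individuals")])
  jsonlite::write_json(summ, file.path(out_dir, "model_summaries.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Behaviour time budgets of a labelled segmentation
#'
#' Fractions of classified GPS segment time spent in each behaviour, with
#' soaring = circular + linear.
#'
#' @param segments labelled segment data.frame.
#' @return named numeric: `circular_soaring`, `linear_soaring`, `gliding`,
#'   `soaring`.
#' @export
time_budget <- function(segments) {
  tb <- tapply(segments$duration, segments$behaviour, sum)
  tb[setdiff(c("circular_soaring", "linear_soaring", "gliding"), names(tb))] <- 0
  tot <- sum(tb)
  out <- tb / tot
  c(out, soaring = unname((tb["circular_soaring"] + tb["linear_soaring"]) / tot))
}
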