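# Static energy landscape: daily mean ODBA against daily mean predicted
# uplift suitability along each bird's route, via a linear mixed model.

#' Build daily energy/suitability records
#'
#' For each individual and calendar day (UTC): the mean per-burst ODBA over
#' flying bursts (height above ground above `min_height` m, which also
#' guarantees a time-matched GPS fix) and the mean predicted uplift
#' probability at those bursts' locations. Bursts falling on unclassified
#' map cells are excluded from the suitability mean (count in attribute
#' `"n_unclassified"`); days with fewer than `min_obs` contributing bursts
#' are dropped.
#'
#' @param acc ACC data.frame from [compute_odba()] and
#'   [geolocate_bursts()].
#' @param map a `uls_suitability` map covering the burst locations.
#' @param min_height flight height threshold (m).
#' @param min_obs minimum bursts per individual-day.
#' @return data.frame: `individual`, `date`, `mean_daily_odba`,
#'   `mean_daily_suitability`, `n_obs`.
#' @export
build_daily_records <- function(acc, map, min_height = 100, min_obs = 5) {
  fly <- acc[!is.na(acc$height_above_ground) &
               acc$height_above_ground > min_height, ]
  if (!nrow(fly)) stop("no qualifying flying bursts", call. = FALSE)
  fly$prob <- raster_extract(map$probability, fly$x_loc, fly$y_loc)
  n_unclassified <- sum(is.na(fly$prob))
  if (n_unclassified)
    message(n_unclassified, " bursts on unclassified cells excluded from ",
            "the suitability mean")
  fly$date <- as.Date(fly$timestamp, tz = "UTC")
  grp <- interaction(fly$individual, fly$date, drop = TRUE)
  recs <- lapply(split(fly, grp), function(d) {
    if (nrow(d) < min_obs) return(NULL)
    data.frame(individual = d$individual[1], date = d$date[1],
               mean_daily_odba = mean(d$odba_mean),
               mean_daily_suitability = mean(d$prob, na.rm = TRUE),
               n_obs = nrow(d))
  })
  out <- do.call(rbind, recs)
  if (is.null(out) || !nrow(out))
    stop("no individual-days with >= ", min_obs, " bursts", call. = FALSE)
  out <- out[!is.na(out$mean_daily_suitability), ]
  rownames(out) <- NULL
  attr(out, "n_unclassified") <- n_unclassified
  out
}

#' Fit the daily energy-expenditure mixed model
#'
#' Linear mixed model of square-root transformed mean daily ODBA on mean
#' daily uplift suitability with a random intercept per individual, fitted
#' by maximum likelihood so the AIC is comparable with the null model (same
#' structure without the suitability slope). A negative slope means birds
#' spend more energy where the landscape offers fewer uplifts.
#'
#' @param records data.frame from [build_daily_records()] (>= 20 records of
#'   >= 2 individuals).
#' @return object of class `uls_energy_fit`: `slope`, `slope_se`,
#'   `ranef_sd`, `aic`, `null_aic`, `delta_aic` (aic - null_aic), `n_obs`,
#'   `n_individuals`, and the two `lme4` fits.
#' @export
fit_energy_model <- function(records) {
  if (nrow(records) < 20 || length(unique(records$individual)) < 2)
    stop("need >= 20 records of >= 2 individuals", call. = FALSE)
  records$sqrt_odba <- sqrt(records$mean_daily_odba)
  fit <- lme4::lmer(sqrt_odba ~ mean_daily_suitability + (1 | individual),
                    data = records, REML = FALSE)
  null <- lme4::lmer(sqrt_odba ~ 1 + (1 | individual),
                     data = records, REML = FALSE)
  co <- summary(fit)$coefficients
  structure(list(
    slope = co["mean_daily_suitability", "Estimate"],
    slope_se = co["mean_daily_suitability", "Std. Error"],
    ranef_sd = sqrt(unname(unlist(lme4::VarCorr(fit)$individual))),
    aic = stats::AIC(fit), null_aic = stats::AIC(null),
    delta_aic = stats::AIC(fit) - stats::AIC(null),
    n_obs = nrow(records),
    n_individuals = length(unique(records$individual)),
    model = fit, null_model = null),
    class = "uls_energy_fit")
}

#' @export
print.uls_energy_fit <- function(x, ...) {
  cat(sprintf(paste0("<uls_energy_fit> slope %.3f +/- %.3f (sqrt-ODBA per ",
                     "unit suitability), dAIC vs null %.2f, n = %d obs / %d ",
                     "individuals\n"),
              x$slope, x$slope_se, x$delta_aic, x$n_obs, x$n_individuals))
  invisible(x)
}

#' Simulate daily energy records with a planted suitability slope
#'
#' Generates records from the model the energy analysis assumes:
#' sqrt(daily ODBA) = intercept + slope * suitability + individual effect +
#' noise, for parameter-recovery checks.
#'
#' @param n_records number of individual-days.
#' @param n_individuals number of individuals.
#' @param slope planted fixed effect (sqrt-ODBA per unit suitability).
#' @param intercept fixed intercept on the sqrt scale.
#' @param intercept_sd between-individual standard deviation.
#' @param resid_sd residual standard deviation.
#' @param seed RNG seed.
#' @return data.frame as from [build_daily_records()].
#' @export
simulate_daily_records <- function(n_records = 800, n_individuals = 59,
                                   slope = -0.67, intercept = 1.3,
                                   intercept_sd = 0.1, resid_sd = 0.25,
                                   seed = 1) {
  set.seed(seed)
  ind <- sprintf("ind%02d", sample.int(n_individuals, n_records, replace = TRUE))
  b <- stats::rnorm(n_individuals, 0, intercept_sd)
  names(b) <- sprintf("ind%02d", seq_len(n_individuals))
  suit <- stats::runif(n_records, 0.05, 0.95)
  sq <- pmax(0.05, intercept + slope * suit + b[ind] +
               stats::rnorm(n_records, 0, resid_sd))
  data.frame(individual = ind,
             date = as.Date("2014-08-01") + seq_len(n_records) %% 60,
             mean_daily_odba = sq^2,
             mean_daily_suitability = suit,
             n_obs = 5L)
}
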