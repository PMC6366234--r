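#' Default configuration for the synthetic landscape generator
#'
#' The landscape is built from smoothed Gaussian random fields on a regular
#' metric grid (default 100 m cells). The true uplift probability surface is
#' a logistic function of standardized roughness, elevation and NDVI plus
#' per-land-use offsets; the true uplift intensity increases with uplift
#' probability and decreases with latitude, and both are forced to zero over
#' water (water bodies suppress thermal uplift).
#'
#' @param res cell size (m).
#' @param autocorr_cells autocorrelation length (cells) of the broad terrain
#'   field.
#' @param autocorr_fine autocorrelation length (cells) of the fine relief
#'   field that generates roughness variation.
#' @param elev_mean,elev_sd elevation mean and standard deviation (m).
#' @param relief_sd standard deviation (m) of the fine-scale relief.
#' @param ndvi_scale slope of the tanh mapping from the NDVI field.
#' @param water_frac,urban_frac,wetland_frac,dump_frac landscape fractions of
#'   the respective land-use classes; the remainder is split among bare soil,
#'   pasture and forest by NDVI terciles.
#' @param coef named numeric: logistic coefficients (`intercept`, and slopes
#'   on standardized `roughness`, `elevation`, `ndvi`) of the true uplift
#'   probability.
#' @param lu_offsets named numeric: additive logit offsets per land-use class
#'   (classes not named get 0).
#' @param w0,w_p intercept (m/s) and slope on uplift probability of the true
#'   uplift intensity.
#' @param dyn_coarse_cells block size (cells) over which the synthetic
#'   dynamic predictors (thermal and orographic uplift potential) are
#'   averaged, emulating the coarse resolution of reanalysis-derived fields.
#' @param dyn_noise_sd noise (in units of each potential) added to the
#'   dynamic predictors.
#' @param w_lat change of uplift intensity per degree of latitude (m/s per
#'   degree, negative: stronger uplift towards the south).
#' @param lon0,lat0 geographic anchor of the metric origin (decimal degrees).
#' @return list of generator parameters.
#' @export
landscape_config <- function(res = 100,
                             autocorr_cells = 12,
                             autocorr_fine = 3,
                             elev_mean = 600, elev_sd = 250,
                             relief_sd = 40,
                             ndvi_scale = 0.7,
                             water_frac = 0.05, urban_frac = 0.03,
                             wetland_frac = 0.04, dump_frac = 0.005,
                             coef = c(intercept = 2.4, roughness = 2.8,
                                      elevation = 2.0, ndvi = -1.3),
                             lu_offsets = c(urban = -2.0, wetland = -1.5,
                                            dump = -1.0),
                             w0 = 0.4, w_p = 1.6, w_lat = -3.0,
                             dyn_coarse_cells = 15, dyn_noise_sd = 0.25,
                             lon0 = 8.0, lat0 = 44.0) {
  as.list(environment())
}

# Block-average a matrix over f x f blocks (ceiling partition) and expand
# back to the original shape: a coarse-resolution view of a field.
coarsen <- function(m, f) {
  gi <- ceiling(seq_len(nrow(m)) / f)
  gj <- ceiling(seq_len(ncol(m)) / f)
  sums <- rowsum(m, gi)
  cnts <- rowsum(matrix(1, nrow(m), ncol(m)), gi)
  sums <- t(rowsum(t(sums), gj)); cnts <- t(rowsum(t(cnts), gj))
  (sums / cnts)[gi, gj, drop = FALSE]
}

# Land-use codes used throughout the package.
LAND_USE_LEVELS <- c("bare_soil", "water", "urban", "wetland", "dump",
                     "pasture", "forest")

# Stationary Gaussian random field by circulant (FFT) convolution of white
# noise with a Gaussian kernel; standardized to mean 0, sd 1.
gaussian_field <- function(nr, nc, range_cells) {
  wn <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_cells <= 0) return(wn)
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- exp(-outer(di^2, dj^2, "+") / (2 * range_cells^2))
  # distances enter separably: exp(-(di^2+dj^2)/2L^2)
  sm <- Re(stats::fft(stats::fft(wn) * stats::fft(k / sum(k)), inverse = TRUE)) /
    (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

# 3x3 max-min with edge replication (no NA border), used only inside the
# generator so the planted surface covers every cell.
rough_padded <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  zp <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  mx <- mn <- z
  mx[] <- -Inf; mn[] <- Inf
  for (dr in 0:2) for (dc in 0:2) {
    w <- zp[dr + seq_len(nr), dc + seq_len(nc)]
    mx <- pmax(mx, w); mn <- pmin(mn, w)
  }
  mx - mn
}

#' Generate a synthetic landscape with a planted uplift field
#'
#' Builds co-registered rasters (DEM, NDVI, categorical land use, urban
#' footprint, latitude) from smoothed Gaussian random fields, plus the true
#' uplift-probability surface `p_uplift` (logistic in standardized roughness,
#' elevation, NDVI and land use) and the true uplift-intensity surface
#' `w_uplift` (m/s, increasing with `p_uplift`, decreasing with latitude).
#' Both uplift surfaces are zero over water. Deterministic given `seed`.
#'
#' @param seed integer RNG seed.
#' @param shape integer 2-vector `c(nrow, ncol)`, at least 50 x 50.
#' @param config list from [landscape_config()].
#' @return object of class `uls_landscape`: a list with `uls_raster` elements
#'   `dem`, `ndvi`, `land_use`, `urban_footprint`, `p_uplift`, `w_uplift`,
#'   `latitude`, `thermal_uplift`, `orographic_uplift`,
#'   plus `ref` (georeference), `config` and `truth`
#'   (the planted coefficients).
#' @export
generate_landscape <- function(seed, shape = c(150, 150),
                               config = landscape_config()) {
  if (length(shape) != 2 || any(shape < 50))
    stop("`shape` must be two integers, each >= 50", call. = FALSE)
  need <- c("intercept", "roughness", "elevation", "ndvi")
  if (!all(need %in% names(config$coef)))
    stop("config$coef must name: ", paste(need, collapse = ", "), call. = FALSE)
  nr <- shape[1]; nc <- shape[2]
  set.seed(seed)

  broad <- gaussian_field(nr, nc, config$autocorr_cells)
  fine <- gaussian_field(nr, nc, config$autocorr_fine)
  dem <- config$elev_mean + config$elev_sd * broad + config$relief_sd * fine
  ndvi <- tanh(config$ndvi_scale * gaussian_field(nr, nc, config$autocorr_cells))
  f_water <- gaussian_field(nr, nc, config$autocorr_cells)
  f_urban <- gaussian_field(nr, nc, config$autocorr_fine * 2)

  lu <- matrix(0L, nr, nc)
  water <- f_water < stats::quantile(f_water, config$water_frac)
  urban <- !water & f_urban > stats::quantile(f_urban, 1 - config$urban_frac)
  wet <- !water & !urban &
    f_water < stats::quantile(f_water, config$water_frac + config$wetland_frac)
  dump <- !water & !urban & !wet &
    f_urban > stats::quantile(f_urban, 1 - config$urban_frac - config$dump_frac)
  rest <- !(water | urban | wet | dump)
  terc <- stats::quantile(ndvi[rest], c(1 / 3, 2 / 3))
  lu[water] <- 2L; lu[urban] <- 3L; lu[wet] <- 4L; lu[dump] <- 5L
  lu[rest & ndvi <= terc[1]] <- 1L                      # bare_soil
  lu[rest & ndvi > terc[1] & ndvi <= terc[2]] <- 6L     # pasture
  lu[rest & ndvi > terc[2]] <- 7L                       # forest

  rough <- rough_padded(dem)
  zs <- function(m) (m - mean(m)) / stats::sd(m)
  lp <- config$coef[["intercept"]] +
    config$coef[["roughness"]] * zs(rough) +
    config$coef[["elevation"]] * zs(dem) +
    config$coef[["ndvi"]] * zs(ndvi)
  for (cls in names(config$lu_offsets))
    lp[lu == match(cls, LAND_USE_LEVELS)] <-
      lp[lu == match(cls, LAND_USE_LEVELS)] + config$lu_offsets[[cls]]
  p <- stats::plogis(lp)
  p[water] <- 0

  ref <- list(lon0 = config$lon0, lat0 = config$lat0,
              lat_mid = config$lat0 + (nr * config$res / 2) / M_PER_DEG_LAT)
  ycent <- (nr - seq_len(nr) + 0.5) * config$res
  latm <- matrix(config$lat0 + ycent / M_PER_DEG_LAT, nr, nc)

  w <- config$w0 + config$w_p * p + config$w_lat * (latm - ref$lat_mid)
  w[w < 0] <- 0
  w[water] <- 0

  # synthetic dynamic predictors: coarse, noisy views of the true uplift
  # field (the coarseness is what makes them weaker predictors than the
  # static layers, as for reanalysis-derived uplift potentials)
  f <- config$dyn_coarse_cells
  thermal <- coarsen(w, f) +
    matrix(stats::rnorm(nr * nc, 0, config$dyn_noise_sd), nr, nc)
  orog <- coarsen(zs(rough) * 0.5 + 0.3 * gaussian_field(nr, nc, config$autocorr_cells), f) +
    matrix(stats::rnorm(nr * nc, 0, config$dyn_noise_sd), nr, nc)

  mk <- function(v, ...) uls_raster(v, xmin = 0, ymin = 0, res = config$res, ...)
  structure(list(
    dem = mk(dem), ndvi = mk(ndvi),
    land_use = mk(lu, categorical = TRUE, levels = LAND_USE_LEVELS),
    urban_footprint = mk((lu == 3L) * 1, categorical = TRUE,
                         levels = c("non_urban", "urban")),
    p_uplift = mk(p), w_uplift = mk(w), latitude = mk(latm),
    thermal_uplift = mk(thermal), orographic_uplift = mk(orog),
    ref = ref, config = config,
    truth = list(coef = config$coef, lu_offsets = config$lu_offsets,
                 w0 = config$w0, w_p = config$w_p, w_lat = config$w_lat)),
    class = "uls_landscape")
}

#' @export
print.uls_landscape <- function(x, ...) {
  g <- raster_grid(x$dem)
  cat(sprintf("<uls_landscape> %d x %d cells @ %g m; mean p_uplift = %.3f\n",
              g$nrow, g$ncol, g$res, mean(x$p_uplift$values)))
  invisible(x)
}

#' Write landscape layers as ESRI ASCII grids
#'
#' One `.asc` file per layer under `dir`.
#'
#' @param landscape a `uls_landscape`.
#' @param dir output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nms <- c("dem", "ndvi", "land_use", "urban_footprint",
           "p_uplift", "w_uplift", "latitude",
           "thermal_uplift", "orographic_uplift")
  paths <- vapply(nms, function(nm)
    write_ascii_grid(landscape[[nm]], file.path(dir, paste0(nm, ".asc"))),
    character(1))
  invisible(paths)
}
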