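# Shared small helpers: bearings, angles, local lon/lat conversion.

# Compass bearing (degrees in [0, 360)) of displacement (dx east, dy north).
bearing_deg <- function(dx, dy) (atan2(dx, dy) * 180 / pi) %% 360

# Smallest absolute angular difference between two bearings, in [0, 180].
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

# Circular standard deviation (degrees) of a vector of angles in degrees.
circ_sd_deg <- function(a) {
  rad <- a * pi / 180
  R <- sqrt(mean(cos(rad))^2 + mean(sin(rad))^2)
  R <- min(max(R, .Machine$double.eps), 1)
  sqrt(-2 * log(R)) * 180 / pi
}

# Metres per degree used by the local equirectangular georeference.
M_PER_DEG_LAT <- 111320

#' Local metric <-> geographic coordinate conversion
#'
#' The simulator and rasters live on a local metric grid anchored at a
#' reference longitude/latitude (equirectangular projection about the centre
#' latitude of the grid). These helpers convert between the two, so tracking
#' CSVs can carry longitude/latitude while all geometry stays metric.
#'
#' @param x,y metric coordinates (m) relative to the grid origin.
#' @param lon,lat geographic coordinates (decimal degrees).
#' @param ref list with `lon0`, `lat0` (geographic coordinates of the metric
#'   origin) and `lat_mid` (latitude at which the east-west scale is fixed).
#' @return data.frame of converted coordinates.
#' @export
local_to_lonlat <- function(x, y, ref) {
  data.frame(
    lon = ref$lon0 + x / (M_PER_DEG_LAT * cos(ref$lat_mid * pi / 180)),
    lat = ref$lat0 + y / M_PER_DEG_LAT)
}

#' @rdname local_to_lonlat
#' @export
lonlat_to_local <- function(lon, lat, ref) {
  data.frame(
    x = (lon - ref$lon0) * M_PER_DEG_LAT * cos(ref$lat_mid * pi / 180),
    y = (lat - ref$lat0) * M_PER_DEG_LAT)
}
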