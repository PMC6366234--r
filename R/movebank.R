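# Movebank-dialect CSV readers and writers for GPS fixes and raw ACC bursts.

MB_TS <- "%Y-%m-%d %H:%M:%OS"

#' Write GPS fixes as a Movebank-dialect CSV
#'
#' Columns: `individual-local-identifier`, `timestamp` (ISO 8601 UTC),
#' `location-long`, `location-lat`, `height-above-ellipsoid`, `ground-speed`.
#'
#' @param gps data.frame with columns `individual`, `timestamp` (POSIXct),
#'   `lon`, `lat`, `height_ellipsoid`, `ground_speed`.
#' @param path output file.
#' @export
write_movebank_gps <- function(gps, path) {
  out <- data.frame(
    `individual-local-identifier` = gps$individual,
    timestamp = format(gps$timestamp, MB_TS, tz = "UTC"),
    `location-long` = gps$lon,
    `location-lat` = gps$lat,
    `height-above-ellipsoid` = gps$height_ellipsoid,
    `ground-speed` = gps$ground_speed,
    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Movebank-dialect GPS CSV
#'
#' @param path CSV file.
#' @param ref optional georeference (as in [local_to_lonlat()]); when given,
#'   metric `x`, `y` columns are added.
#' @return data.frame with columns `individual`, `timestamp`, `lon`, `lat`,
#'   `height_ellipsoid`, `ground_speed` (and `x`, `y` if `ref` given).
#' @export
read_movebank_gps <- function(path, ref = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  out <- data.frame(
    individual = as.character(d[["individual-local-identifier"]]),
    timestamp = as.POSIXct(d[["timestamp"]], format = MB_TS, tz = "UTC"),
    lon = d[["location-long"]], lat = d[["location-lat"]],
    height_ellipsoid = d[["height-above-ellipsoid"]],
    ground_speed = d[["ground-speed"]])
  if (!is.null(ref)) {
    xy <- lonlat_to_local(out$lon, out$lat, ref)
    out$x <- xy$x; out$y <- xy$y
  }
  out
}

#' Group 1 Hz fixes into bursts
#'
#' Assigns a `burst_id` to maximal runs of consecutive fixes of one
#' individual spaced at the nominal 1 s interval; plain (low-rate) fixes get
#' `NA`.
#'
#' @param gps GPS data.frame (as from [read_movebank_gps()]).
#' @param max_gap maximum spacing (s) within a burst.
#' @param min_fixes minimum run length to call a burst.
#' @return `gps` with a `burst_id` column, sorted by individual and time.
#' @export
identify_bursts <- function(gps, max_gap = 1, min_fixes = 30) {
  gps <- gps[order(gps$individual, gps$timestamp), ]
  dt <- c(Inf, diff(as.numeric(gps$timestamp)))
  newid <- c(TRUE, gps$individual[-1] != gps$individual[-nrow(gps)])
  brk <- newid | dt > max_gap
  run <- cumsum(brk)
  len <- ave(run, run, FUN = length)
  gps$burst_id <- ifelse(len >= min_fixes,
                         sprintf("%s_r%05d", gps$individual, run), NA)
  gps
}

#' Write accelerometer bursts as a Movebank-dialect CSV
#'
#' Raw samples are stored XYZ-interleaved in an `eobs-accelerations-raw`
#' column, with the per-axis sampling frequency alongside.
#'
#' @param acc data.frame with columns `individual`, `timestamp`, `acc_hz` and
#'   list-column `samples` (n x 3 matrices).
#' @param path output file.
#' @export
write_movebank_acc <- function(acc, path) {
  raw <- vapply(acc$samples, function(m)
    paste(sprintf("%.4f", as.vector(t(m))), collapse = " "), character(1))
  out <- data.frame(
    `individual-local-identifier` = acc$individual,
    timestamp = format(acc$timestamp, MB_TS, tz = "UTC"),
    `eobs-accelerations-raw` = raw,
    `eobs-acceleration-sampling-frequency-per-axis` = acc$acc_hz,
    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a Movebank-dialect accelerometer CSV
#'
#' @param path CSV file.
#' @return data.frame with `individual`, `timestamp`, `acc_hz` and
#'   list-column `samples` of n x 3 matrices (axes in columns x, y, z).
#' @export
read_movebank_acc <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  samples <- lapply(strsplit(as.character(d[["eobs-accelerations-raw"]]), " +"),
                    function(v) {
                      m <- matrix(as.numeric(v), ncol = 3, byrow = TRUE)
                      colnames(m) <- c("x", "y", "z")
                      m
                    })
  out <- data.frame(
    individual = as.character(d[["individual-local-identifier"]]),
    timestamp = as.POSIXct(d[["timestamp"]], format = MB_TS, tz = "UTC"),
    acc_hz = d[["eobs-acceleration-sampling-frequency-per-axis"]])
  out$samples <- samples
  out
}
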