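# Accelerometer processing: ODBA/DBA statistics, k-means activity classes,
# burst geolocation and flapping (uplift absence) selection.

#' ODBA and heave-axis DBA statistics of accelerometer bursts
#'
#' The static component of each axis is the burst mean of that axis (bursts
#' last 3.8 s); the dynamic component is the sample minus the static. The
#' per-sample overall dynamic body acceleration (ODBA) is the sum over the
#' three axes of the absolute dynamic components. Mean, sum and standard
#' deviation are computed over the per-sample ODBA values and over the
#' absolute dynamic heave (z) components.
#'
#' @param acc data.frame with list-column `samples` of n x 3 matrices (40
#'   samples per axis).
#' @param n_samples required samples per axis.
#' @return `acc` with numeric columns `odba_mean`, `odba_sum`, `odba_sd`,
#'   `dba_z_mean`, `dba_z_sum`, `dba_z_sd`.
#' @export
compute_odba <- function(acc, n_samples = 40) {
  stats_ <- t(vapply(acc$samples, function(m) {
    if (is.null(m) || anyNA(m) || nrow(m) != n_samples)
      stop("each burst needs exactly ", n_samples,
           " complete samples per axis", call. = FALSE)
    dyn <- abs(sweep(m, 2, colMeans(m)))
    odba <- rowSums(dyn)
    c(mean(odba), sum(odba), stats::sd(odba),
      mean(dyn[, 3]), sum(dyn[, 3]), stats::sd(dyn[, 3]))
  }, numeric(6)))
  colnames(stats_) <- c("odba_mean", "odba_sum", "odba_sd",
                        "dba_z_mean", "dba_z_sum", "dba_z_sd")
  cbind(acc, as.data.frame(stats_))
}

#' Classify burst activity by k-means on the ODBA/DBA statistics
#'
#' The six per-burst statistics are standardized and clustered with k-means
#' (k = 3, 25 restarts); clusters are ranked by their centroid mean ODBA and
#' named `least`, `intermediate`, `most` active.
#'
#' @param acc data.frame from [compute_odba()].
#' @param k number of clusters.
#' @param seed RNG seed for the k-means restarts.
#' @return `acc` with an `activity_class` factor column
#'   (levels least < intermediate < most).
#' @export
classify_activity <- function(acc, k = 3, seed = 1) {
  feats <- c("odba_mean", "odba_sum", "odba_sd",
             "dba_z_mean", "dba_z_sum", "dba_z_sd")
  X <- as.matrix(acc[, feats])
  if (nrow(X) < k) stop("need at least ", k, " bursts", call. = FALSE)
  if (nrow(unique(X)) < k)
    stop("fewer distinct feature vectors than clusters: degenerate input",
         call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  Xs <- scale(X[, sds > 0, drop = FALSE])
  set.seed(seed)
  km <- stats::kmeans(Xs, centers = k, nstart = 25, iter.max = 100)
  ord <- order(tapply(acc$odba_mean, km$cluster, mean))
  lev <- c("least", "intermediate", "most")[seq_len(k)]
  acc$activity_class <- factor(lev[match(km$cluster, ord)], levels = lev,
                               ordered = TRUE)
  acc
}

#' Geolocate accelerometer bursts from the GPS track
#'
#' Burst location is the time-linear interpolation between the bracketing
#' GPS fixes of the same individual. Height above ground is assigned only
#' when the nearest fix is closer than `max_gap` seconds, as that fix's
#' ellipsoid height minus the DEM elevation at the burst location; otherwise
#' it is missing. Bursts outside the individual's GPS time span keep a
#' missing location.
#'
#' @param acc ACC data.frame (`individual`, `timestamp`).
#' @param gps GPS data.frame (`individual`, `timestamp`, `x`, `y`,
#'   `height_ellipsoid`).
#' @param dem `uls_raster` of ground elevation.
#' @param max_gap maximum time difference (s) to the nearest fix for a
#'   height assignment.
#' @return `acc` with `x_loc`, `y_loc`, `height_above_ground` columns.
#' @export
geolocate_bursts <- function(acc, gps, dem, max_gap = 30) {
  acc$x_loc <- acc$y_loc <- acc$height_above_ground <- NA_real_
  for (id in unique(acc$individual)) {
    ai <- which(acc$individual == id)
    g <- gps[gps$individual == id, ]
    if (!nrow(g)) next
    g <- g[order(g$timestamp), ]
    gt <- as.numeric(g$timestamp)
    at <- as.numeric(acc$timestamp[ai])
    inside <- at >= gt[1] & at <= gt[length(gt)]
    if (!any(inside)) next
    xi <- stats::approx(gt, g$x, xout = at[inside], ties = "ordered")$y
    yi <- stats::approx(gt, g$y, xout = at[inside], ties = "ordered")$y
    acc$x_loc[ai[inside]] <- xi
    acc$y_loc[ai[inside]] <- yi
    near <- findInterval(at[inside], gt, all.inside = TRUE)
    gap_lo <- abs(at[inside] - gt[near])
    gap_hi <- abs(gt[pmin(near + 1, length(gt))] - at[inside])
    nearest <- ifelse(gap_lo <= gap_hi, near, pmin(near + 1, length(gt)))
    gap <- pmin(gap_lo, gap_hi)
    ok <- gap < max_gap
    if (any(ok)) {
      ground <- raster_extract(dem, xi[ok], yi[ok])
      acc$height_above_ground[ai[inside][ok]] <-
        g$height_ellipsoid[nearest[ok]] - ground
    }
  }
  acc
}

#' Select flapping bursts as uplift absences
#'
#' Bursts in the most-active class with height above ground greater than the
#' threshold mark the absence of uplift (powered flight where no uplift was
#' available); the height filter excludes flapping tied to take-off.
#'
#' @param acc data.frame from [classify_activity()] and
#'   [geolocate_bursts()].
#' @param min_height height-above-ground threshold (m).
#' @return data.frame of absence observations: `individual`, `timestamp`,
#'   `x`, `y`, `presence` (0).
#' @export
select_flapping <- function(acc, min_height = 100) {
  sel <- !is.na(acc$height_above_ground) &
    acc$activity_class == "most" & acc$height_above_ground > min_height
  out <- data.frame(
    individual = acc$individual[sel], timestamp = acc$timestamp[sel],
    x = acc$x_loc[sel], y = acc$y_loc[sel], presence = 0L)
  rownames(out) <- NULL
  out
}
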