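# GPS burst segmentation: per-fix metrics, 15 s segments, EMbC-style
# clustering into flight behaviours, label smoothing, soaring-event
# extraction.

#' Per-fix vertical speed and turning angle
#'
#' Vertical speed at fix i is the forward height difference
#' (h\[i+1\] - h\[i\]) / dt; the turning angle at fix i is the absolute change
#' in ground-track heading at that fix, in degrees within \[0, 180\]. First
#' and last fixes carry NA where the quantity is undefined. Headings use
#' planar bearings: metric `x`, `y` columns are used when present, otherwise
#' longitude/latitude are projected equirectangularly about the burst
#' centroid (burst extents are far below the scale where this matters).
#'
#' @param burst data.frame of one burst, ordered in time, with columns
#'   `timestamp`, `height_ellipsoid`, and `x`,`y` or `lon`,`lat`; >= 3 rows.
#' @return `burst` with `vspeed` (m/s) and `turn` (degrees) columns.
#' @export
compute_fix_metrics <- function(burst) {
  n <- nrow(burst)
  if (n < 3) stop("burst needs at least 3 fixes", call. = FALSE)
  tt <- as.numeric(burst$timestamp)
  dt <- diff(tt)
  if (any(dt == 0)) stop("duplicate timestamps in burst", call. = FALSE)
  if (is.null(burst$x) || is.null(burst$y)) {
    latm <- mean(burst$lat)
    burst$x <- (burst$lon - mean(burst$lon)) * M_PER_DEG_LAT * cos(latm * pi / 180)
    burst$y <- (burst$lat - latm) * M_PER_DEG_LAT
  }
  burst$vspeed <- c(diff(burst$height_ellipsoid) / dt, NA)
  hd <- bearing_deg(diff(burst$x), diff(burst$y))
  burst$turn <- c(NA, ang_diff(hd[-1], hd[-(n - 1)]), NA)
  burst
}

#' Cut a burst into consecutive 15 s flight segments
#'
#' Non-overlapping windows from the first fix; each segment carries the mean
#' vertical speed and the sum of absolute turning angles of its fixes, plus
#' the fix-position centroid. The turning angle at a window's first fix is
#' the corner between the last step of the previous window and the first
#' step of this one; it is attributed to the previous window, so that a
#' full soaring circle sums to ~360 degrees and a straight glide entered
#' from a circle stays near 0. A trailing remainder shorter than the window
#' is dropped. Bursts shorter than 120 s are not segmentation-eligible.
#'
#' @param burst data.frame from [compute_fix_metrics()].
#' @param window segment length (s).
#' @param min_duration minimum burst duration (s) for eligibility.
#' @return data.frame of segments: `burst_id`, `individual`, `seg`,
#'   `t_start`, `t_end`, `duration`, `mean_vspeed`, `cum_turn`, `n_fix`,
#'   `x`, `y` (fix centroid), and `behaviour_true` (majority truth label)
#'   when the burst carries a `behaviour` column.
#' @export
build_segments <- function(burst, window = 15, min_duration = 120) {
  tt <- as.numeric(burst$timestamp)
  dur <- tt[length(tt)] - tt[1] + 1
  if (dur < min_duration) return(NULL)
  el <- tt - tt[1]
  k <- floor(el / window)
  kturn <- floor((el - 1) / window)   # first-fix corner -> previous window
  nseg <- floor(dur / window)
  tsel <- kturn >= 0 & kturn < nseg & !is.na(burst$turn)
  turn_sums <- vapply(split(burst$turn[tsel], kturn[tsel]), sum, numeric(1))
  full <- k < nseg
  b <- burst[full, ]; k <- k[full]
  segs <- lapply(split(seq_len(nrow(b)), k), function(ii) {
    d <- b[ii, ]
    data.frame(
      burst_id = if (!is.null(d$burst_id)) d$burst_id[1] else NA,
      individual = if (!is.null(d$individual)) d$individual[1] else NA,
      seg = k[ii[1]] + 1L,
      t_start = d$timestamp[1], t_end = d$timestamp[nrow(d)],
      duration = window,
      mean_vspeed = mean(d$vspeed, na.rm = TRUE),
      cum_turn = {
        kk <- as.character(k[ii[1]])
        if (kk %in% names(turn_sums)) unname(turn_sums[kk]) else 0
      },
      n_fix = nrow(d),
      x = mean(d$x), y = mean(d$y),
      behaviour_true = if (!is.null(d$behaviour))
        names(which.max(table(d$behaviour))) else NA_character_)
  })
  do.call(rbind, segs)
}

#' Segment every eligible burst of a GPS dataset
#'
#' Applies [compute_fix_metrics()] and [build_segments()] per `burst_id`.
#'
#' @param gps GPS data.frame with a `burst_id` column (see
#'   [identify_bursts()]).
#' @param window,min_duration as in [build_segments()].
#' @return pooled segment data.frame.
#' @export
segment_bursts <- function(gps, window = 15, min_duration = 120) {
  gps <- gps[!is.na(gps$burst_id), ]
  out <- lapply(split(gps, gps$burst_id), function(b) {
    b <- b[order(b$timestamp), ]
    if (nrow(b) < 3) return(NULL)
    build_segments(compute_fix_metrics(b), window, min_duration)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Diagonal-covariance Gaussian log density.
dnorm2_log <- function(x1, x2, m1, m2, s1, s2)
  stats::dnorm(x1, m1, s1, log = TRUE) + stats::dnorm(x2, m2, s2, log = TRUE)

#' Classify flight segments by expectation-maximization binary clustering
#'
#' Fits a four-component Gaussian mixture (diagonal covariances) on the two
#' segment metrics (mean vertical speed, absolute cumulative turning angle),
#' constrained so the components occupy the four quadrants of two
#' per-variable low/high delimiters. The delimiters are re-derived at every
#' EM step as the midpoint between the low-group and high-group component
#' means of each variable, and component means are kept on their side.
#' Labels follow the fitted delimiters: segments on the high side of the
#' turning delimiter are `circular_soaring`; segments on the low side are
#' linear flight, split by the sign of their mean vertical speed into
#' `linear_soaring` (> 0) and `gliding` (<= 0). If the turning variable
#' shows no meaningful low/high separation (group means closer than
#' `min_turn_sep`), the data are treated as a single turning regime: all
#' linear if the pooled mean turning is below 180 degrees, all circular
#' otherwise.
#'
#' @param segments segment data.frame from [segment_bursts()]; >= 20 rows.
#' @param max_iter maximum EM iterations.
#' @param tol log-likelihood convergence tolerance.
#' @param min_turn_sep minimum separation (degrees) between low- and
#'   high-turning group means for a two-regime interpretation.
#' @return `segments` with a `behaviour` column; the fitted mixture
#'   (means, sds, weights, delimiters, log-likelihood, iterations) is
#'   attached as attribute `"embc_fit"`.
#' @export
embc_classify <- function(segments, max_iter = 200, tol = 1e-6,
                          min_turn_sep = 45) {
  v <- segments$mean_vspeed; u <- segments$cum_turn
  n <- length(v)
  if (n < 20) stop("need at least 20 segments", call. = FALSE)
  if (stats::sd(v) == 0 || stats::sd(u) == 0)
    stop("zero variance in a clustering metric: degenerate input", call. = FALSE)

  # component quadrants: (vspeed level, turn level)
  quad <- cbind(vlow = c(TRUE, FALSE, TRUE, FALSE),
                ulow = c(TRUE, TRUE, FALSE, FALSE))
  dv <- stats::median(v); du <- stats::median(u)
  sfloor_v <- 1e-3 * stats::sd(v); sfloor_u <- 1e-3 * stats::sd(u)
  mu_v <- mu_u <- s_v <- s_u <- w <- numeric(4)
  for (kk in 1:4) {
    sel <- (if (quad[kk, "vlow"]) v <= dv else v > dv) &
      (if (quad[kk, "ulow"]) u <= du else u > du)
    if (sum(sel) < 2) sel <- rep(TRUE, n)   # empty quadrant: start from pooled
    mu_v[kk] <- mean(v[sel]); mu_u[kk] <- mean(u[sel])
    s_v[kk] <- max(stats::sd(v[sel]), sfloor_v)
    s_u[kk] <- max(stats::sd(u[sel]), sfloor_u)
    w[kk] <- max(sum(sel), 1) / n
  }
  w <- w / sum(w)

  ll_old <- -Inf; iter <- 0L; converged <- FALSE
  R <- matrix(0, n, 4)
  while (iter < max_iter) {
    iter <- iter + 1L
    lg <- sapply(1:4, function(kk)
      log(w[kk]) + dnorm2_log(v, u, mu_v[kk], mu_u[kk], s_v[kk], s_u[kk]))
    m <- apply(lg, 1, max)
    R <- exp(lg - m)
    rs <- rowSums(R)
    ll <- sum(m + log(rs))
    R <- R / rs
    nk <- colSums(R)
    w <- nk / n
    mu_v <- colSums(R * v) / nk
    mu_u <- colSums(R * u) / nk
    s_v <- pmax(sqrt(colSums((matrix(v, n, 4) - matrix(mu_v, n, 4, byrow = TRUE))^2 * R) / nk),
                sfloor_v)
    s_u <- pmax(sqrt(colSums((matrix(u, n, 4) - matrix(mu_u, n, 4, byrow = TRUE))^2 * R) / nk),
                sfloor_u)
    # delimiters: midpoints between the low- and high-group component means
    dv <- (mean(mu_v[quad[, "vlow"]]) + mean(mu_v[!quad[, "vlow"]])) / 2
    du <- (mean(mu_u[quad[, "ulow"]]) + mean(mu_u[!quad[, "ulow"]])) / 2
    # keep components on their side of the delimiters
    mu_v[quad[, "vlow"]] <- pmin(mu_v[quad[, "vlow"]], dv)
    mu_v[!quad[, "vlow"]] <- pmax(mu_v[!quad[, "vlow"]], dv)
    mu_u[quad[, "ulow"]] <- pmin(mu_u[quad[, "ulow"]], du)
    mu_u[!quad[, "ulow"]] <- pmax(mu_u[!quad[, "ulow"]], du)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (!converged)
    stop(sprintf(paste0("EMbC EM did not converge in %d iterations ",
                        "(last log-likelihood %.4f, change %.2e)"),
                 max_iter, ll, ll - ll_old), call. = FALSE)

  turn_sep <- mean(mu_u[!quad[, "ulow"]]) - mean(mu_u[quad[, "ulow"]])
  high_turn <- if (turn_sep < min_turn_sep) {
    rep(mean(u) > 180, n)        # single turning regime
  } else u > du
  segments$behaviour <- ifelse(high_turn, "circular_soaring",
                               ifelse(v > 0, "linear_soaring", "gliding"))
  attr(segments, "embc_fit") <- list(
    mu_vspeed = mu_v, mu_turn = mu_u, sd_vspeed = s_v, sd_turn = s_u,
    weights = w, delim_vspeed = dv, delim_turn = du,
    loglik = ll, iterations = iter, converged = converged,
    turn_separation = turn_sep)
  segments
}

# Mode of a character vector; ties return NA (caller keeps the original).
label_mode <- function(x) {
  tab <- table(x)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) top else NA_character_
}

#' Smooth behaviour labels along a burst
#'
#' One left-to-right pass: a segment whose label differs from both immediate
#' neighbours is reclassified to the modal label of the two segments before
#' and after it (self excluded, window truncated at the burst edges). A tied
#' vote keeps the original label; the first and last segments have only one
#' immediate neighbour, so the rule never applies to them.
#'
#' @param labels character vector of labels, in temporal order within one
#'   burst.
#' @return smoothed label vector.
#' @export
smooth_labels <- function(labels) {
  n <- length(labels)
  if (n < 3) return(labels)
  out <- labels
  for (i in 2:(n - 1)) {
    nb <- c(out[i - 1], out[i + 1])
    if (all(nb != out[i])) {
      win <- out[setdiff(intersect((i - 2):(i + 2), seq_len(n)), i)]
      m <- label_mode(win)
      if (!is.na(m)) out[i] <- m
    }
  }
  out
}

#' Apply the label smoother burst by burst
#'
#' @param segments labelled segment data.frame (with `burst_id`,
#'   `behaviour`).
#' @return `segments` with smoothed `behaviour`.
#' @export
smooth_segments <- function(segments) {
  ord <- order(segments$burst_id, segments$t_start)
  segments <- segments[ord, ]
  segments$behaviour <- unlist(lapply(
    split(segments$behaviour, segments$burst_id), smooth_labels),
    use.names = FALSE)
  segments
}

#' Extract soaring events (uplift presences) from labelled segments
#'
#' Circular and linear soaring are pooled; gliding is excluded. Maximal runs
#' of soaring segments of one individual are merged into one event when
#' separated by less than `min_gap` seconds; events whose total soaring
#' duration is not longer than `min_duration` are discarded. The event
#' centroid is the fix-level mean position of the member segments.
#'
#' @param segments labelled segment data.frame.
#' @param min_gap merge gap (s).
#' @param min_duration minimum soaring duration (s), exclusive.
#' @return data.frame of events: `individual`, `t_start`, `t_end`,
#'   `duration` (s of soaring), `n_seg`, `x`, `y`, `mean_vspeed`.
#' @export
extract_soaring_events <- function(segments, min_gap = 60, min_duration = 30) {
  so <- segments[segments$behaviour %in% c("circular_soaring", "linear_soaring"), ]
  if (!nrow(so)) return(so[0, c("individual", "t_start", "t_end")])
  so <- so[order(so$individual, so$t_start), ]
  newind <- c(TRUE, so$individual[-1] != so$individual[-nrow(so)])
  gap <- c(Inf, as.numeric(so$t_start[-1]) - as.numeric(so$t_end[-nrow(so)]))
  ev <- cumsum(newind | gap >= min_gap)
  out <- lapply(split(seq_len(nrow(so)), ev), function(ii) {
    d <- so[ii, ]
    wt <- d$n_fix
    data.frame(
      individual = d$individual[1],
      t_start = d$t_start[1], t_end = d$t_end[nrow(d)],
      duration = sum(d$duration), n_seg = nrow(d),
      x = sum(d$x * wt) / sum(wt), y = sum(d$y * wt) / sum(wt),
      mean_vspeed = sum(d$mean_vspeed * wt) / sum(wt))
  })
  out <- do.call(rbind, out)
  out <- out[out$duration > min_duration, ]
  rownames(out) <- NULL
  out
}

#' Full GPS segmentation pipeline
#'
#' Metrics, 15 s segments, EMbC-style classification pooled across bursts,
#' burst-wise label smoothing, and soaring-event extraction.
#'
#' @param gps GPS data.frame with `burst_id`.
#' @param window,min_duration segmentation window and burst eligibility (s).
#' @param ... passed to [embc_classify()].
#' @return list with `segments` (labelled, smoothed) and `events`.
#' @export
segment_tracks <- function(gps, window = 15, min_duration = 120, ...) {
  segs <- segment_bursts(gps, window, min_duration)
  segs <- embc_classify(segs, ...)
  fit <- attr(segs, "embc_fit")
  segs <- smooth_segments(segs)
  events <- extract_soaring_events(segs)
  list(segments = segs, events = events, embc_fit = fit)
}
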