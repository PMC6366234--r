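#' Sampling schedule of the tracking devices
#'
#' Defaults follow the loggers' duty cycle: one plain GPS fix every 5 min,
#' 1 Hz GPS bursts every 15 min lasting 300 s, and a tri-axial accelerometer
#' burst every 10 min of 3.8 s at 10.54 Hz (40 samples per axis).
#'
#' @param gps_fix_interval seconds between plain GPS fixes.
#' @param gps_burst_interval seconds between starts of 1 Hz bursts.
#' @param gps_burst_duration duration (s) of each 1 Hz burst; 0 disables
#'   burst recording (plain fixes only), which speeds up simulations that
#'   only need the attempt/behaviour record.
#' @param acc_interval seconds between accelerometer bursts.
#' @param acc_hz accelerometer sampling rate (Hz).
#' @param acc_samples samples per axis per burst.
#' @param hours_per_day daily flight window length (h).
#' @param n_days number of simulated flight days.
#' @param day_start_utc start of the daily flight window (hour, UTC).
#' @param start_date first flight day (Date or string).
#' @return list of schedule parameters.
#' @export
schedule_config <- function(gps_fix_interval = 300,
                            gps_burst_interval = 900,
                            gps_burst_duration = 300,
                            acc_interval = 600,
                            acc_hz = 10.54,
                            acc_samples = 40,
                            hours_per_day = 8,
                            n_days = 4,
                            day_start_utc = 8,
                            start_date = "2014-08-01") {
  as.list(environment())
}

#' Flight behaviour and sensor-noise configuration of the simulator
#'
#' Behaviour runs on a 15 s tick (the duration of one soaring circle). At
#' each decision point the bird draws Bernoulli(p_uplift) at its current
#' cell. On success it soars (circling, or climbing straight with
#' probability `frac_linear_soar`) for `soar_ticks` ticks at a climb rate
#' drawn around the cell's true uplift intensity, then glides straight and
#' descending for `glide_ticks` ticks. On failure it flaps (level, powered)
#' for `flap_seconds`, then glides for the remainder of one tick, and tries
#' again. Bout durations are aligned to the tick so 15 s track segments are
#' behaviourally pure.
#'
#' @param tick behaviour tick (s).
#' @param soar_ticks,glide_ticks bout lengths in ticks.
#' @param flap_seconds powered-flight duration within a failed tick (s).
#' @param frac_linear_soar share of soaring bouts that are linear climbs.
#' @param circle_period,circle_radius soaring-circle period (s) and radius
#'   range (m).
#' @param climb_sd bird-to-bird spread (m/s) of realized climb rate around
#'   the cell's true uplift intensity.
#' @param glide_speed,flap_speed,linear_soar_speed ground speeds (m/s).
#' @param soar_drift horizontal drift of the circling bird (m/s).
#' @param glide_sink sink rate while gliding (m/s).
#' @param flap_climb climb rate while flapping (m/s).
#' @param agl_min,agl_max,agl_start operating band of height above ground (m).
#' @param heading_sd between-bout heading change (degrees, s.d.).
#' @param gps_xy_sd,gps_z_sd marginal GPS noise (m) on position and height.
#' @param gps_ar1 lag-1 autocorrelation of the GPS error process at 1 Hz
#'   (GPS error is strongly autocorrelated, which keeps track geometry
#'   realistic at high sampling rates).
#' @param speed_sd noise (m/s) on the reported instantaneous ground speed.
#' @param acc_flap_amp,acc_flap_amp_sd flapping oscillation amplitude on the
#'   heave (z) axis (g) and its burst-to-burst spread.
#' @param acc_flap_freq wingbeat frequency (Hz).
#' @param acc_soar_sd,acc_glide_sd dynamic-acceleration noise (g) while
#'   soaring / gliding.
#' @param acc_base_sd sensor noise floor (g), all axes.
#' @return list of flight parameters.
#' @export
flight_config <- function(tick = 15,
                          soar_ticks = 6, glide_ticks = 4,
                          flap_seconds = 6,
                          frac_linear_soar = 0.22,
                          circle_period = 15, circle_radius = c(20, 40),
                          climb_sd = 0.2,
                          glide_speed = 14, flap_speed = 11,
                          linear_soar_speed = 12,
                          soar_drift = 2,
                          glide_sink = 1.95, flap_climb = 1.0,
                          agl_min = 200, agl_max = 1500, agl_start = 600,
                          heading_sd = 25,
                          gps_xy_sd = 3, gps_z_sd = 5, gps_ar1 = 0.95,
                          speed_sd = 0.3,
                          acc_flap_amp = 1.2, acc_flap_amp_sd = 0.1,
                          acc_flap_freq = 3.5,
                          acc_soar_sd = 0.03, acc_glide_sd = 0.08,
                          acc_base_sd = 0.02) {
  as.list(environment())
}

# AR(1) noise with marginal sd `sd` and lag-1 correlation `rho`.
ar1_noise <- function(n, sd, rho) {
  if (n == 0) return(numeric(0))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) for (i in 2:n) x[i] <- rho * x[i - 1] + e[i]
  x
}

# Simulate the bout sequence of one bird-day. Returns a data.frame of bouts
# (behaviour, start second, duration, start position/heading/height and
# motion parameters) plus the attempt record.
simulate_day <- function(landscape, fl, day_seconds, x0, y0, h0, heading0) {
  P <- landscape$p_uplift
  W <- landscape$w_uplift
  D <- landscape$dem
  xmax <- raster_xmax(P); ymax <- raster_ymax(P)
  margin <- 10 * P$res
  tick <- fl$tick

  nmax <- ceiling(day_seconds / tick) + 8L
  bouts <- vector("list", 3L * nmax)
  att <- matrix(NA_real_, nmax, 5L)  # t, row, col, p, success
  nb <- 0L; na_ <- 0L
  x <- x0; y <- y0; h <- h0; heading <- heading0
  t <- 0

  add_bout <- function(behaviour, t0, dur, x, y, h, heading, pars) {
    nb <<- nb + 1L
    bouts[[nb]] <<- list(behaviour = behaviour, t0 = t0, dur = dur,
                         x = x, y = y, h = h, heading = heading, pars = pars)
  }

  while (t < day_seconds) {
    # keep the bird inside the landscape: steer towards the centre near edges
    if (x < margin || x > xmax - margin || y < margin || y > ymax - margin)
      heading <- bearing_deg(xmax / 2 - x, ymax / 2 - y) +
        stats::rnorm(1, 0, fl$heading_sd)
    x <- min(max(x, 0), xmax); y <- min(max(y, 0), ymax)
    rc <- raster_cell(P, x, y)
    p <- P$values[rc$row, rc$col]
    ground <- D$values[rc$row, rc$col]
    success <- stats::runif(1) < p
    na_ <- na_ + 1L
    att[na_, ] <- c(t, rc$row, rc$col, p, success)

    if (success) {
      w <- max(0.2, stats::rnorm(1, W$values[rc$row, rc$col], fl$climb_sd))
      nt <- fl$soar_ticks
      room <- (ground + fl$agl_max) - h
      nt <- max(1L, min(nt, floor(room / (tick * w))))
      dur <- nt * tick
      if (stats::runif(1) < fl$frac_linear_soar) {
        add_bout("linear_soaring", t, dur, x, y, h, heading,
                 list(v = fl$linear_soar_speed, vz = w))
        x <- x + fl$linear_soar_speed * dur * sin(heading * pi / 180)
        y <- y + fl$linear_soar_speed * dur * cos(heading * pi / 180)
      } else {
        dirn <- sample(c(-1, 1), 1)
        # phase chosen so the bird enters (and, after whole circles, exits)
        # the circle tangentially along its current heading
        add_bout("circular_soaring", t, dur, x, y, h, heading,
                 list(r = stats::runif(1, fl$circle_radius[1], fl$circle_radius[2]),
                      period = fl$circle_period, dirn = dirn,
                      drift = fl$soar_drift, vz = w,
                      phase = (heading - dirn * 90) * pi / 180))
        x <- x + fl$soar_drift * dur * sin(heading * pi / 180)
        y <- y + fl$soar_drift * dur * cos(heading * pi / 180)
      }
      h <- h + w * dur
      t <- t + dur
      # glide bout
      heading <- heading + stats::rnorm(1, 0, fl$heading_sd)
      ng <- fl$glide_ticks
      room <- h - (ground + fl$agl_min)
      ng <- max(1L, min(ng, floor(room / (tick * fl$glide_sink))))
      gdur <- ng * tick
      add_bout("gliding", t, gdur, x, y, h, heading,
               list(v = fl$glide_speed, vz = -fl$glide_sink))
      x <- x + fl$glide_speed * gdur * sin(heading * pi / 180)
      y <- y + fl$glide_speed * gdur * cos(heading * pi / 180)
      h <- h - fl$glide_sink * gdur
      t <- t + gdur
    } else {
      fs <- fl$flap_seconds
      add_bout("flapping", t, fs, x, y, h, heading,
               list(v = fl$flap_speed, vz = fl$flap_climb))
      x <- x + fl$flap_speed * fs * sin(heading * pi / 180)
      y <- y + fl$flap_speed * fs * cos(heading * pi / 180)
      h <- h + fl$flap_climb * fs
      t <- t + fs
      gs <- tick - fs
      if (h - fl$glide_sink * gs < ground + fl$agl_min) {
        # too low to glide: keep flapping (and climbing) through the tick
        add_bout("flapping", t, gs, x, y, h, heading,
                 list(v = fl$flap_speed, vz = fl$flap_climb))
        x <- x + fl$flap_speed * gs * sin(heading * pi / 180)
        y <- y + fl$flap_speed * gs * cos(heading * pi / 180)
        h <- h + fl$flap_climb * gs
      } else {
        add_bout("gliding", t, gs, x, y, h, heading,
                 list(v = fl$glide_speed, vz = -fl$glide_sink))
        x <- x + fl$glide_speed * gs * sin(heading * pi / 180)
        y <- y + fl$glide_speed * gs * cos(heading * pi / 180)
        h <- h - fl$glide_sink * gs
      }
      t <- t + gs
      heading <- heading + stats::rnorm(1, 0, fl$heading_sd)
    }
  }
  att <- att[seq_len(na_), , drop = FALSE]
  colnames(att) <- c("t", "row", "col", "p", "success")
  list(bouts = bouts[seq_len(nb)], attempts = as.data.frame(att),
       state = list(x = x, y = y, h = h, heading = heading))
}

# True position/height/speed/behaviour at given seconds within one bout.
bout_path <- function(bout, secs) {
  tt <- secs - bout$t0
  p <- bout$pars
  hd <- bout$heading * pi / 180
  if (bout$behaviour == "circular_soaring") {
    # circle centre placed so the path enters (and, after whole circles,
    # exits) exactly at the bird's state position: no jumps at transitions
    cx <- (bout$x - p$r * sin(p$phase)) + p$drift * tt * sin(hd)
    cy <- (bout$y - p$r * cos(p$phase)) + p$drift * tt * cos(hd)
    ph <- p$phase + p$dirn * 2 * pi * tt / p$period
    x <- cx + p$r * sin(ph)
    y <- cy + p$r * cos(ph)
    v <- sqrt((2 * pi * p$r / p$period)^2 + p$drift^2)
  } else {
    x <- bout$x + p$v * tt * sin(hd)
    y <- bout$y + p$v * tt * cos(hd)
    v <- p$v
  }
  data.frame(t = secs, x = x, y = y, h = bout$h + p$vz * tt,
             speed = v, behaviour = bout$behaviour)
}

#' Simulate stork GPS and accelerometer data over a landscape
#'
#' Runs the behaviour model of [flight_config()] for `n_birds` individuals
#' over the landscape, then samples the trajectory on the device schedule of
#' [schedule_config()]: 1 Hz GPS bursts, plain 5 min fixes, and 3.8 s ACC
#' bursts whose dynamic acceleration is high while flapping and low while
#' soaring or gliding. Ground-truth behaviour labels are recorded for every
#' fix, every ACC burst, and every uplift attempt (cell, true probability,
#' outcome). Deterministic given `seed`.
#'
#' @param landscape a `uls_landscape`.
#' @param n_birds number of individuals (>= 1).
#' @param seed integer RNG seed.
#' @param schedule list from [schedule_config()].
#' @param flight list from [flight_config()].
#' @return object of class `uls_simulation` with elements:
#'   `gps` (data.frame: individual, timestamp, lon, lat, x, y,
#'   height_ellipsoid, ground_speed, burst_id, behaviour),
#'   `acc` (data.frame: individual, timestamp, x, y true location, behaviour,
#'   with list-column `samples` of 40 x 3 matrices and `acc_hz`),
#'   `attempts` (data.frame of uplift attempts with truth), `ref`, `truth`.
#' @export
simulate_tracks <- function(landscape, n_birds, seed,
                            schedule = schedule_config(),
                            flight = flight_config()) {
  stopifnot(inherits(landscape, "uls_landscape"))
  if (n_birds < 1) stop("n_birds must be >= 1", call. = FALSE)
  set.seed(seed)
  sc <- schedule; fl <- flight
  P <- landscape$p_uplift
  day_seconds <- sc$hours_per_day * 3600
  t0_date <- as.Date(sc$start_date)

  gps_all <- list(); acc_all <- list(); att_all <- list()
  gk <- 0L; ak <- 0L; tk <- 0L

  for (b in seq_len(n_birds)) {
    id <- sprintf("bird%02d", b)
    # start well inside the landscape
    x <- stats::runif(1, 0.25, 0.75) * raster_xmax(P)
    y <- stats::runif(1, 0.25, 0.75) * raster_ymax(P)
    heading <- stats::runif(1, 0, 360)
    h <- raster_extract(landscape$dem, x, y) + fl$agl_start
    acc_phase <- stats::runif(1, 0, sc$acc_interval)

    for (d in seq_len(sc$n_days)) {
      day0 <- as.POSIXct(t0_date + (d - 1), tz = "UTC") + sc$day_start_utc * 3600
      sim <- simulate_day(landscape, fl, day_seconds, x, y, h, heading)
      x <- sim$state$x; y <- sim$state$y; h <- sim$state$h
      heading <- sim$state$heading
      b0 <- vapply(sim$bouts, `[[`, numeric(1), "t0")
      b1 <- b0 + vapply(sim$bouts, `[[`, numeric(1), "dur")

      path_at <- function(secs) {
        idx <- findInterval(secs, b0)
        out <- do.call(rbind, lapply(split(seq_along(secs), idx), function(ii) {
          bout_path(sim$bouts[[idx[ii[1]]]], secs[ii])
        }))
        out[order(out$t), , drop = FALSE]
      }

      # -- GPS: 1 Hz burst windows plus plain fixes ----------------------
      if (sc$gps_burst_duration > 0) {
        bstart <- seq(0, day_seconds - 1, by = sc$gps_burst_interval)
        burst_secs <- lapply(seq_along(bstart), function(i)
          seq(bstart[i], min(bstart[i] + sc$gps_burst_duration - 1,
                             day_seconds - 1)))
      } else burst_secs <- list()
      plain <- seq(0, day_seconds - 1, by = sc$gps_fix_interval)
      inburst <- if (length(burst_secs)) unlist(burst_secs) else numeric(0)
      plain <- setdiff(plain, inburst)

      secs <- sort(c(inburst, plain))
      if (length(secs)) {
        pth <- path_at(secs)
        n <- nrow(pth)
        pth$x_obs <- pth$x + ar1_noise(n, fl$gps_xy_sd, fl$gps_ar1)
        pth$y_obs <- pth$y + ar1_noise(n, fl$gps_xy_sd, fl$gps_ar1)
        pth$h_obs <- pth$h + ar1_noise(n, fl$gps_z_sd, fl$gps_ar1)
        pth$speed_obs <- pmax(0, pth$speed + stats::rnorm(n, 0, fl$speed_sd))
        burst_id <- rep(NA_character_, n)
        for (i in seq_along(burst_secs)) {
          m <- pth$t %in% burst_secs[[i]]
          burst_id[m] <- sprintf("%s_d%02d_b%03d", id, d, i)
        }
        ll <- local_to_lonlat(pth$x_obs, pth$y_obs, landscape$ref)
        gk <- gk + 1L
        gps_all[[gk]] <- data.frame(
          individual = id, timestamp = day0 + pth$t,
          lon = ll$lon, lat = ll$lat, x = pth$x_obs, y = pth$y_obs,
          height_ellipsoid = pth$h_obs, ground_speed = pth$speed_obs,
          burst_id = burst_id, behaviour = pth$behaviour)
      }

      # -- ACC bursts ----------------------------------------------------
      acc_end <- day_seconds - ceiling(sc$acc_samples / sc$acc_hz)
      astart <- if (acc_phase <= acc_end)
        seq(acc_phase, acc_end, by = sc$acc_interval) else numeric(0)
      if (length(astart)) {
        tau <- (seq_len(sc$acc_samples) - 1) / sc$acc_hz
        for (a0 in astart) {
          st <- a0 + tau
          pth <- path_at(floor(st))
          beh <- pth$behaviour
          z <- matrix(stats::rnorm(sc$acc_samples * 3, 0, fl$acc_base_sd),
                      sc$acc_samples, 3)
          z[, 3] <- z[, 3] + 1  # gravity on the heave axis
          fli <- beh == "flapping"
          if (any(fli)) {
            A <- max(0.5, stats::rnorm(1, fl$acc_flap_amp, fl$acc_flap_amp_sd))
            ph <- stats::runif(3, 0, 2 * pi)
            z[fli, 1] <- z[fli, 1] + 0.30 * A * sin(2 * pi * fl$acc_flap_freq * st[fli] + ph[1])
            z[fli, 2] <- z[fli, 2] + 0.25 * A * sin(2 * pi * fl$acc_flap_freq * st[fli] + ph[2])
            z[fli, 3] <- z[fli, 3] + A * sin(2 * pi * fl$acc_flap_freq * st[fli] + ph[3])
          }
          gl <- beh == "gliding"
          if (any(gl)) z[gl, ] <- z[gl, ] + stats::rnorm(sum(gl) * 3, 0, fl$acc_glide_sd)
          so <- beh %in% c("circular_soaring", "linear_soaring")
          if (any(so)) z[so, ] <- z[so, ] + stats::rnorm(sum(so) * 3, 0, fl$acc_soar_sd)
          maj <- names(which.max(table(beh)))
          mid <- pth[ceiling(nrow(pth) / 2), ]
          ak <- ak + 1L
          acc_all[[ak]] <- data.frame(
            individual = id, timestamp = day0 + a0,
            x = mid$x, y = mid$y, behaviour = maj)
          acc_all[[ak]]$samples <- list(z)
        }
      }

      tk <- tk + 1L
      at <- sim$attempts
      at$individual <- id; at$day <- d
      att_all[[tk]] <- at
    }
  }

  gps <- do.call(rbind, gps_all)
  acc <- do.call(rbind, acc_all)
  acc$acc_hz <- sc$acc_hz
  structure(list(
    gps = gps, acc = acc, attempts = do.call(rbind, att_all),
    ref = landscape$ref, schedule = sc, flight = fl,
    truth = landscape$truth),
    class = "uls_simulation")
}

#' @export
print.uls_simulation <- function(x, ...) {
  cat(sprintf("<uls_simulation> %d birds, %d GPS fixes, %d ACC bursts\n",
              length(unique(x$gps$individual)), nrow(x$gps), nrow(x$acc)))
  tb <- prop.table(table(x$gps$behaviour))
  cat("  fix behaviour mix:",
      paste(sprintf("%s %.2f", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}
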