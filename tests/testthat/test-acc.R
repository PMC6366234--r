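# ODBA statistics, k-means activity classes, burst geolocation, flapping
# selection.

test_that("ODBA follows its definition on constructed bursts", {
  t0 <- as.POSIXct("2014-08-01 10:00:00", tz = "UTC")
  mk <- function(m) {
    d <- data.frame(individual = "b1", timestamp = t0)
    d$samples <- list(m)
    d
  }
  # constant signal: all statistics zero
  cst <- compute_odba(mk(matrix(c(1, 0.2, -0.5), 40, 3, byrow = TRUE)))
  expect_equal(unlist(cst[, c("odba_mean", "odba_sum", "odba_sd",
                              "dba_z_mean", "dba_z_sum", "dba_z_sd")]),
               setNames(rep(0, 6), c("odba_mean", "odba_sum", "odba_sd",
                                     "dba_z_mean", "dba_z_sum", "dba_z_sd")))
  # scaling an axis about its mean exactly doubles the ODBA sum
  set.seed(41)
  m <- random_burst()
  m2 <- m
  for (a in 1:3) m2[, a] <- mean(m[, a]) + 2 * (m[, a] - mean(m[, a]))
  expect_equal(compute_odba(mk(m2))$odba_sum, 2 * compute_odba(mk(m))$odba_sum,
               tolerance = 1e-12)
  # 4-sample toy burst: x = (1,3,1,3), y and z constant -> ODBA (1,1,1,1)
  toy <- cbind(x = c(1, 3, 1, 3), y = rep(2, 4), z = rep(1, 4))
  out <- compute_odba(mk(toy), n_samples = 4)
  expect_equal(out$odba_sum, 4)
  expect_equal(out$odba_mean, 1)
  expect_equal(out$odba_sd, 0)
  # adding a constant offset to any axis leaves ODBA unchanged
  m3 <- m; m3[, 2] <- m3[, 2] + 5
  expect_equal(compute_odba(mk(m3))$odba_sum, compute_odba(mk(m))$odba_sum,
               tolerance = 1e-12)
  # missing / wrong-length samples are an input error
  expect_error(compute_odba(mk(m[1:30, ])), "40")
  mna <- m; mna[3, 2] <- NA
  expect_error(compute_odba(mk(mna)), "complete")
})

test_that("activity k-means recovers three planted tiers and ranks them", {
  set.seed(42)
  t0 <- as.POSIXct("2014-08-01 10:00:00", tz = "UTC")
  tier <- rep(c("least", "intermediate", "most"), each = 100)
  amp <- c(least = 0.03, intermediate = 0.2, most = 1.2)
  acc <- data.frame(individual = "b1", timestamp = t0 + seq_len(300) * 600)
  acc$samples <- lapply(tier, function(tt) {
    tau <- seq_len(40) / 10.54
    cbind(rnorm(40, 0, 0.02) + 0.3 * amp[tt] * sin(2 * pi * 3.5 * tau),
          rnorm(40, 0, 0.02) + 0.25 * amp[tt] * sin(2 * pi * 3.5 * tau + 1),
          1 + rnorm(40, 0, 0.02) + amp[tt] * sin(2 * pi * 3.5 * tau + 2))
  })
  acc <- classify_activity(compute_odba(acc), seed = 1)
  expect_gte(mean(as.character(acc$activity_class) == tier), 0.98)
  # ranking by centroid mean ODBA
  agg <- tapply(acc$odba_mean, acc$activity_class, mean)
  expect_true(agg[["least"]] < agg[["intermediate"]])
  expect_true(agg[["intermediate"]] < agg[["most"]])
  # identical bursts are degenerate
  same <- acc[rep(1, 10), ]
  same$samples <- rep(acc$samples[1], 10)
  expect_error(classify_activity(compute_odba(same)), "degenerate")
})

test_that("burst geolocation interpolates in time and applies the 30 s rule", {
  t0 <- as.POSIXct("2014-08-01 10:00:00", tz = "UTC")
  dem <- uls_raster(matrix(380, 60, 60), res = 100)
  gps <- data.frame(
    individual = "b1",
    timestamp = t0 + c(0, 40, 1000),
    x = c(1000, 3000, 3000), y = c(1000, 1000, 1000),
    height_ellipsoid = c(500, 500, 520))
  acc <- data.frame(individual = "b1",
                    timestamp = t0 + c(20, 550, 2000))
  acc$samples <- replicate(3, random_burst(), simplify = FALSE)
  out <- geolocate_bursts(acc, gps, dem)
  # midway in time between fixes at x 1000 and 3000 -> x 2000
  expect_equal(out$x_loc[1], 2000)
  # nearest fix 20 s away: height = ellipsoid height - DEM = 500 - 380
  expect_equal(out$height_above_ground[1], 120)
  # nearest fix 450 s away: location interpolated, height missing
  expect_equal(out$x_loc[2], 3000)
  expect_true(is.na(out$height_above_ground[2]))
  # outside the GPS span: location missing
  expect_true(is.na(out$x_loc[3]))
})

test_that("flapping absences need the most-active class above 100 m", {
  t0 <- as.POSIXct("2014-08-01 10:00:00", tz = "UTC")
  acc <- data.frame(
    individual = "b1", timestamp = t0 + 1:4,
    activity_class = factor(c("most", "least", "most", "most"),
                            levels = c("least", "intermediate", "most"),
                            ordered = TRUE),
    x_loc = 1:4, y_loc = 1:4,
    height_above_ground = c(50, 500, 150, NA))
  out <- select_flapping(acc)
  expect_equal(nrow(out), 1)        # only most-active at 150 m
  expect_equal(out$x, 3)
  expect_true(all(out$presence == 0))
})

test_that("flapping bursts carry more dynamic acceleration than soaring", {
  sim <- tiny_sim()
  acc <- compute_odba(sim$acc)
  fl <- acc$odba_mean[acc$behaviour == "flapping"]
  so <- acc$odba_mean[acc$behaviour %in% c("circular_soaring", "linear_soaring")]
  expect_gt(length(fl), 3)
  expect_lt(stats::wilcox.test(fl, so, alternative = "greater")$p.value, 0.01)
})
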