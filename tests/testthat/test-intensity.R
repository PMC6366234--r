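# Vertical-speed gridding, percentile filtering, the GAM intensity model,
# framework comparison and the restricted intensity map.

make_cells <- function(n, seed = 1, latrange = c(44, 44.15)) {
  set.seed(seed)
  data.frame(
    row = 1, col = seq_len(n), n = 5,
    aspect = runif(n, 0, 360), ndvi = runif(n, -0.5, 0.8),
    dem = runif(n, 200, 1200), roughness = runif(n, 0, 60),
    latitude = runif(n, latrange[1], latrange[2]),
    thermal_uplift = rnorm(n), orographic_uplift = rnorm(n),
    land_use = factor(sample(c("bare_soil", "pasture", "forest"), n, TRUE),
                      levels = c("bare_soil", "pasture", "forest")))
}

test_that("gridding pools positive vertical speeds per cell", {
  L <- tiny_landscape()
  stack <- landscape_stack(L)
  t0 <- as.POSIXct("2014-08-01 08:00:00", tz = "UTC")
  # a hand-built burst whose climb alternates +1, +3 within one cell and
  # dips negative in another
  h <- c(100, 101, 104, 105, 108, 107, 110)
  b <- data.frame(individual = "b1", burst_id = "r1",
                  timestamp = t0 + seq_along(h) - 1,
                  x = c(450, 450, 450, 450, 450, 1450, 1450),
                  y = rep(450, length(h)),
                  height_ellipsoid = h, ground_speed = 10)
  cells <- grid_vertical_speeds(b, stack)
  c1 <- cells[cells$x == 450, ]
  expect_equal(c1$mean_vspeed, mean(c(1, 3, 1, 3)))  # negatives excluded
  expect_equal(c1$n, 4)
  c2 <- cells[cells$x == 1450, ]
  expect_equal(c2$mean_vspeed, 3)                    # the -1 is dropped
  expect_true(all(c("dem", "ndvi", "roughness", "aspect", "latitude",
                    "land_use") %in% names(cells)))
  expect_equal(levels(cells$land_use)[1], "bare_soil")
})

test_that("the percentile filter matches a sort-and-count oracle", {
  set.seed(61)
  cells <- data.frame(mean_vspeed = sample(seq(0.01, 100, length.out = 10000)))
  out <- filter_percentile(cells, 99.97)
  # brute force: interpolated order statistic, then count strictly above
  s <- sort(cells$mean_vspeed)
  h <- (10000 - 1) * 0.9997 + 1
  cut <- s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  expect_equal(attr(out, "n_removed"), sum(cells$mean_vspeed > cut))
  expect_equal(attr(out, "n_removed"), 3)            # 10000 x 0.0003
  # all equal: nothing exceeds the percentile
  same <- data.frame(mean_vspeed = rep(2, 200))
  expect_equal(nrow(filter_percentile(same)), 200)
  # q = 100 removes nothing
  expect_equal(nrow(filter_percentile(cells, 100)), 10000)
  expect_error(filter_percentile(cells[1:50, , drop = FALSE]), "100")
})

test_that("the GAM recovers a planted cyclic aspect effect, periodically", {
  cells <- make_cells(900, seed = 62)
  f <- function(a) 0.35 * sin(2 * pi * a / 360)
  set.seed(62)
  cells$mean_vspeed <- (1.2 + f(cells$aspect) + rnorm(900, 0, 0.1))^2
  fit <- fit_intensity_gam(cells, "static")
  grid <- data.frame(aspect = seq(0, 360, by = 5),
                     ndvi = 0.2, dem = 700, roughness = 30,
                     latitude = 44.07, land_use = factor("bare_soil",
                       levels = levels(cells$land_use)))
  pr <- predict(fit$gam, grid, type = "terms")
  sm <- pr[, "s(aspect)"]
  expect_gte(cor(sm, f(grid$aspect)), 0.9)
  expect_lt(abs(sm[1] - sm[length(sm)]), 1e-6)      # periodic by construction
  expect_gt(fit$adj_r2, 0.5)
})

test_that("a near-constant response shrinks all smooths to nothing", {
  cells <- make_cells(600, seed = 63)
  set.seed(63)
  cells$mean_vspeed <- 1.44 + rnorm(600, 0, 0.005)  # predictor-free noise
  fit <- suppressWarnings(fit_intensity_gam(cells, "static"))
  # penalized parts shrink away; each smooth keeps only its unpenalized
  # linear null space (~1 EDF)
  expect_true(all(summary(fit$gam)$edf < 1.3))
  expect_lt(abs(fit$adj_r2), 0.05)
})

test_that("AIC ranking identifies the generating framework", {
  cells <- make_cells(800, seed = 64)
  set.seed(64)
  # static + dynamic signal: the combined framework generates the data
  mu <- 1.2 + 0.3 * sin(2 * pi * cells$aspect / 360) +
    2e-4 * (cells$dem - 700) + 0.15 * cells$thermal_uplift +
    0.08 * cells$orographic_uplift
  cells$mean_vspeed <- pmax(0.05, mu + rnorm(800, 0, 0.12))^2
  fits <- lapply(c("static", "dynamic", "combined"),
                 function(fw) fit_intensity_gam(cells, fw))
  rk <- compare_frameworks(fits)
  expect_equal(rk$framework[1], "combined")
  expect_equal(rk$delta_aic[1], 0)
  # a duplicated fit ties at delta 0
  rk2 <- compare_frameworks(list(fits[[3]], fits[[3]]))
  expect_equal(rk2$delta_aic, c(0, 0))
  # different response data are not comparable
  other <- fit_intensity_gam(make_cells(700, seed = 65, latrange = c(44, 44.1)) |>
                               transform(mean_vspeed = runif(700, 0.5, 2)),
                             "static")
  expect_error(compare_frameworks(list(fits[[1]], other)), "same response")
})

test_that("the intensity map predicts only on suitable, in-range cells", {
  L <- tiny_landscape()
  stack <- landscape_stack(L)
  sim <- tiny_sim()
  cells <- grid_vertical_speeds(sim$gps, stack)
  cells <- filter_percentile(cells)
  fit <- fit_intensity_gam(cells, "static")
  # a synthetic suitability map: suitable north half, unsuitable south,
  # a block of unclassified cells
  g <- stack$grid
  bm <- matrix(0, g$nrow, g$ncol); bm[1:(g$nrow / 2), ] <- 1
  bm[1:10, 1:10] <- NA
  suit <- structure(list(
    probability = uls_raster(bm, res = g$res),
    binary = uls_raster(bm, res = g$res),
    mask = uls_raster(matrix(as.numeric(is.na(bm)), g$nrow, g$ncol), res = g$res),
    threshold = 0.9), class = "uls_suitability")
  imap <- predict_intensity_map(fit, stack, suit)
  v <- imap$values
  expect_true(all(is.na(v[bm == 0 | is.na(bm)])))
  expect_true(all(v[!is.na(v)] >= 0))               # squared back-transform
  # latitude restriction: cells outside the training band are missing
  lat <- stack$layers$latitude$values
  out_lat <- lat < fit$training_ranges$latitude[1] |
    lat > fit$training_ranges$latitude[2]
  expect_true(all(is.na(v[out_lat])))
  expect_error(predict_intensity_map(fit, stack, "nope"), "uls_suitability")
})
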