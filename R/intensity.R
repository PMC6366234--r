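# Uplift intensity: grid-averaged positive vertical speeds, outlier
# filtering, GAM fits under the three predictor frameworks, and the
# suitability-restricted intensity map.

#' Grid-average positive vertical speeds
#'
#' Computes fix-level vertical speeds for every eligible 1 Hz burst, keeps
#' only the positive values (climbing flight, the uplift-intensity signal),
#' pools them across individuals and averages per 100 m grid cell over the
#' whole period. Each cell is annotated with the predictor values at its
#' centre, including latitude.
#'
#' @param gps GPS data.frame with `burst_id` (see [identify_bursts()]).
#' @param stack a `uls_stack` with the intensity predictors (`dem`, `ndvi`,
#'   `roughness`, `aspect`, `land_use`, `latitude`; optionally
#'   `thermal_uplift`, `orographic_uplift`).
#' @return data.frame of cells: `row`, `col`, `mean_vspeed`, `n`, predictor
#'   columns (`land_use` as a factor with `bare_soil` reference).
#' @export
grid_vertical_speeds <- function(gps, stack) {
  gps <- gps[!is.na(gps$burst_id), ]
  fixes <- do.call(rbind, lapply(split(gps, gps$burst_id), function(b) {
    if (nrow(b) < 3) return(NULL)
    b <- compute_fix_metrics(b[order(b$timestamp), ])
    b[!is.na(b$vspeed) & b$vspeed > 0, c("x", "y", "vspeed")]
  }))
  ref_r <- stack$layers[[1]]
  rc <- raster_cell(ref_r, fixes$x, fixes$y)
  ok <- !is.na(rc$row)
  fixes <- fixes[ok, ]; rc <- rc[ok, ]
  key <- (rc$row - 1L) * stack$grid$ncol + rc$col
  mv <- tapply(fixes$vspeed, key, mean)
  nn <- tapply(fixes$vspeed, key, length)
  keys <- as.integer(names(mv))
  cells <- data.frame(
    row = (keys - 1L) %/% stack$grid$ncol + 1L,
    col = (keys - 1L) %% stack$grid$ncol + 1L,
    mean_vspeed = as.numeric(mv), n = as.integer(nn))
  cells$x <- ref_r$xmin + (cells$col - 0.5) * ref_r$res
  cells$y <- ref_r$ymin + (stack$grid$nrow - cells$row + 0.5) * ref_r$res
  for (nm in intersect(c("dem", "ndvi", "roughness", "aspect", "latitude",
                         "thermal_uplift", "orographic_uplift"),
                       names(stack$layers)))
    cells[[nm]] <- raster_extract(stack$layers[[nm]], cells$x, cells$y)
  lu <- raster_extract(stack$layers$land_use, cells$x, cells$y)
  lev <- stack$layers$land_use$levels
  cells$land_use <- stats::relevel(factor(lev[lu], levels = lev),
                                   ref = "bare_soil")
  rownames(cells) <- NULL
  cells
}

#' Remove extreme grid-cell vertical speeds
#'
#' Drops cells whose mean vertical speed exceeds the `q`-th percentile of
#' all cells (default 99.97, removing implausible climb rates).
#'
#' @param cells data.frame from [grid_vertical_speeds()] (>= 100 rows).
#' @param q percentile in (0, 100\].
#' @return filtered data.frame; the number removed is attribute
#'   `"n_removed"`.
#' @export
filter_percentile <- function(cells, q = 99.97) {
  if (nrow(cells) < 100) stop("need at least 100 cells", call. = FALSE)
  cut <- stats::quantile(cells$mean_vspeed, q / 100)
  keep <- cells$mean_vspeed <= cut
  if (any(!keep))
    message(sum(!keep), " cells above the ", q, " percentile removed")
  out <- cells[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Fit the GAM uplift-intensity model
#'
#' Gaussian GAM on the square-root transformed mean vertical speed. In the
#' static and combined frameworks, aspect enters as a cyclic cubic spline
#' (period 0-360 degrees), NDVI, elevation, roughness and latitude as
#' thin-plate splines, and land use as parametric coefficients against the
#' bare-soil reference; the dynamic and combined frameworks add the thermal
#' and orographic uplift potentials as parametric terms. Smoothing
#' parameters are selected by REML.
#'
#' @param cells data.frame from [filter_percentile()] (>= 500 rows).
#' @param framework `"static"`, `"dynamic"` or `"combined"`.
#' @param k_tp,k_cc basis sizes for thin-plate and cyclic smooths.
#' @param method smoothing-parameter selection (`"REML"` or `"GCV.Cp"`).
#' @return object of class `uls_gam_fit`: the `mgcv::gam` object plus
#'   `framework`, `aic`, `adj_r2`, `n`, and the training ranges used for
#'   map prediction.
#' @export
fit_intensity_gam <- function(cells, framework = "static",
                              k_tp = 10, k_cc = 8, method = "REML") {
  if (nrow(cells) < 500) stop("need at least 500 cells", call. = FALSE)
  cells$sqrt_vspeed <- sqrt(cells$mean_vspeed)
  cells$land_use <- droplevels(cells$land_use)
  smooths <- paste0(
    "s(aspect, bs = 'cc', k = ", k_cc, ") + s(ndvi, k = ", k_tp,
    ") + s(dem, k = ", k_tp, ") + s(roughness, k = ", k_tp,
    ") + s(latitude, k = ", k_tp, ")")
  rhs <- switch(framework,
                static = paste("land_use +", smooths),
                dynamic = "thermal_uplift + orographic_uplift",
                combined = paste("land_use +", smooths,
                                 "+ thermal_uplift + orographic_uplift"),
                stop("unknown framework", call. = FALSE))
  use <- stats::complete.cases(
    cells[, intersect(c("aspect", "ndvi", "dem", "roughness", "latitude",
                        "land_use", "thermal_uplift", "orographic_uplift",
                        "sqrt_vspeed"), names(cells))])
  d <- cells[use, ]
  fit <- mgcv::gam(stats::as.formula(paste("sqrt_vspeed ~", rhs)),
                   data = d, method = method,
                   knots = list(aspect = c(0, 360)))
  cont <- intersect(c("aspect", "ndvi", "dem", "roughness", "latitude",
                      "thermal_uplift", "orographic_uplift"), names(d))
  if (framework == "dynamic")
    cont <- c("thermal_uplift", "orographic_uplift")
  ranges <- lapply(cont, function(nm) range(d[[nm]]))
  names(ranges) <- cont
  structure(list(gam = fit, framework = framework,
                 aic = stats::AIC(fit),
                 adj_r2 = summary(fit)$r.sq,
                 n = nrow(d),
                 training_ranges = ranges,
                 land_use_levels = levels(d$land_use)),
            class = "uls_gam_fit")
}

#' @export
print.uls_gam_fit <- function(x, ...) {
  cat(sprintf("<uls_gam_fit> %s framework, n = %d, AIC = %.2f, adj R2 = %.3f\n",
              x$framework, x$n, x$aic, x$adj_r2))
  invisible(x)
}

#' Rank intensity-model frameworks by AIC
#'
#' @param fits list of `uls_gam_fit` objects fitted to the same response.
#' @return data.frame `framework`, `aic`, `delta_aic`, `adj_r2`, best first.
#' @export
compare_frameworks <- function(fits) {
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1)
    stop("fits were not made on the same response data", call. = FALSE)
  out <- data.frame(
    framework = vapply(fits, `[[`, character(1), "framework"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    adj_r2 = vapply(fits, `[[`, numeric(1), "adj_r2"))
  out <- out[order(out$aic), ]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  out
}

#' Predict the uplift intensity map on suitable cells
#'
#' Predicts the square-root-scale intensity and back-transforms by squaring,
#' only on cells that the suitability map classifies as suitable, whose
#' predictor values fall within the fit's training ranges, and whose
#' latitude lies within the training latitude range; all other cells are
#' missing.
#'
#' @param fit a `uls_gam_fit` (static framework for a static map).
#' @param stack the predictor `uls_stack`.
#' @param suitability a `uls_suitability` map.
#' @return `uls_raster` of predicted uplift intensity (m/s).
#' @export
predict_intensity_map <- function(fit, stack, suitability) {
  if (!inherits(suitability, "uls_suitability"))
    stop("`suitability` must be a uls_suitability map", call. = FALSE)
  cc <- raster_coords(stack$layers[[1]])
  newd <- data.frame(row.names = seq_len(nrow(cc)))
  for (nm in intersect(c("aspect", "ndvi", "dem", "roughness", "latitude",
                         "thermal_uplift", "orographic_uplift"),
                       names(stack$layers)))
    newd[[nm]] <- raster_extract(stack$layers[[nm]], cc$x, cc$y)
  lu <- raster_extract(stack$layers$land_use, cc$x, cc$y)
  lev <- stack$layers$land_use$levels
  newd$land_use <- factor(lev[lu], levels = fit$land_use_levels)

  suitable <- suitability$binary$values[cbind(cc$row, cc$col)] == 1
  ok <- !is.na(suitable) & suitable
  vars <- all.vars(stats::formula(fit$gam))[-1]
  for (nm in intersect(vars, names(newd)))
    ok <- ok & !is.na(newd[[nm]])
  for (nm in names(fit$training_ranges)) {
    rg <- fit$training_ranges[[nm]]
    ok <- ok & !is.na(newd[[nm]]) & newd[[nm]] >= rg[1] & newd[[nm]] <= rg[2]
  }
  if ("land_use" %in% vars) ok <- ok & !is.na(newd$land_use)
  pred <- rep(NA_real_, nrow(newd))
  if (any(ok))
    pred[ok] <- pmax(0, stats::predict(fit$gam, newd[ok, , drop = FALSE]))^2
  g <- stack$grid
  m <- matrix(NA_real_, g$nrow, g$ncol)
  m[cbind(cc$row, cc$col)] <- pred
  uls_raster(m, stack$layers[[1]]$xmin, stack$layers[[1]]$ymin, g$res)
}
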