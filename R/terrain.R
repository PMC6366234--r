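#' Predictor stack: co-registered raster layers on one grid
#'
#' @param layers named list of `uls_raster` objects sharing one grid.
#' @param training_ranges optional named list of `c(min, max)` per continuous
#'   layer, recorded at model-training points and used to mask extrapolation
#'   when predicting maps.
#' @return an object of class `uls_stack`.
#' @export
uls_stack <- function(layers, training_ranges = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  g0 <- layers[[1]]
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "uls_raster"))
      stop("layer '", nm, "' is not a uls_raster", call. = FALSE)
    if (!same_grid(layers[[nm]], g0))
      stop("layer '", nm, "' is not co-registered with the first layer",
           call. = FALSE)
  }
  structure(list(layers = layers, grid = raster_grid(g0),
                 training_ranges = training_ranges),
            class = "uls_stack")
}

#' @export
print.uls_stack <- function(x, ...) {
  cat(sprintf("<uls_stack> %d layers, %d x %d cells @ %g m\n",
              length(x$layers), x$grid$nrow, x$grid$ncol, x$grid$res))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Names of the continuous (non-categorical) layers of a stack
#' @param stack a `uls_stack`.
#' @export
continuous_layers <- function(stack) {
  names(stack$layers)[!vapply(stack$layers, `[[`, logical(1), "categorical")]
}

# Shift a matrix by (dr, dc), padding with NA; dr > 0 brings the row above
# (the northern neighbour) into position.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

# The eight neighbour matrices plus centre, in compass order.
neigh_stack <- function(m) {
  list(nw = shift_mat(m, 1, 1),  n = shift_mat(m, 1, 0),  ne = shift_mat(m, 1, -1),
       w  = shift_mat(m, 0, 1),  c = m,                   e  = shift_mat(m, 0, -1),
       sw = shift_mat(m, -1, 1), s = shift_mat(m, -1, 0), se = shift_mat(m, -1, -1))
}

#' Derive static terrain predictors from a DEM
#'
#' Computes, on the DEM's own grid: slope and aspect by Horn's 3x3
#' finite-difference method, roughness (3x3 max minus min), topographic
#' position index (centre minus mean of the 8 neighbours), slope unevenness
#' (3x3 standard deviation of slope) and aspect unevenness (3x3 circular
#' standard deviation of aspect). Edge cells and any cell whose 3x3 window
#' touches a missing value are set missing; the aspect of flat cells is
#' undefined and set missing.
#'
#' @param dem a `uls_raster` of elevations (m), at least 3x3 cells.
#' @return a `uls_stack` with layers `dem`, `slope` (degrees), `aspect`
#'   (compass degrees in \[0, 360)), `roughness` (m), `tpi` (m),
#'   `slope_unevenness` (degrees), `aspect_unevenness` (degrees).
#' @export
derive_terrain <- function(dem) {
  stopifnot(inherits(dem, "uls_raster"))
  z <- dem$values
  if (nrow(z) < 3 || ncol(z) < 3)
    stop("DEM must have at least 3x3 cells", call. = FALSE)
  res <- dem$res
  nb <- neigh_stack(z)

  dzdx <- ((nb$ne + 2 * nb$e + nb$se) - (nb$nw + 2 * nb$w + nb$sw)) / (8 * res)
  dzdy <- ((nb$nw + 2 * nb$n + nb$ne) - (nb$sw + 2 * nb$s + nb$se)) / (8 * res)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  aspect <- bearing_deg(-dzdx, -dzdy)
  aspect[!is.na(slope) & slope == 0] <- NA   # flat: aspect undefined

  arr <- simplify2array(nb)                  # nr x nc x 9
  roughness <- apply(arr, c(1, 2), function(v) max(v) - min(v))
  tpi <- z - apply(simplify2array(nb[names(nb) != "c"]), c(1, 2), mean)

  slope_sd <- apply(simplify2array(neigh_stack(slope)), c(1, 2), stats::sd)
  asp_nb <- simplify2array(neigh_stack(aspect))
  aspect_sd <- apply(asp_nb, c(1, 2), function(v)
    if (anyNA(v)) NA_real_ else circ_sd_deg(v))

  mk <- function(v) { dimnames(v) <- NULL; uls_raster(v, dem$xmin, dem$ymin, res) }
  uls_stack(list(
    dem = mk(z), slope = mk(slope), aspect = mk(aspect),
    roughness = mk(roughness), tpi = mk(tpi),
    slope_unevenness = mk(slope_sd), aspect_unevenness = mk(aspect_sd)))
}

# Block-aggregate a matrix by integer factor f: continuous -> mean of
# non-missing cells; categorical -> majority vote (ties to the smallest code).
block_aggregate <- function(m, f, categorical = FALSE) {
  nr <- floor(nrow(m) / f); nc <- floor(ncol(m) / f)
  m <- m[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    blk <- m[(i - 1) * f + seq_len(f), (j - 1) * f + seq_len(f)]
    blk <- blk[!is.na(blk)]
    if (!length(blk)) next
    out[i, j] <- if (categorical) {
      tab <- table(blk)
      as.numeric(names(tab)[which.max(tab)])   # which.max: first = smallest code
    } else mean(blk)
  }
  out
}

#' Co-register raster layers onto a common target-resolution grid
#'
#' Continuous layers finer than the target are block-averaged; categorical
#' layers are resampled by majority vote. Layers coarser than the target are
#' upsampled by nearest neighbour with a warning. All inputs must overlap
#' spatially; the output covers the snapped intersection of their extents.
#'
#' @param rasters named list of `uls_raster` objects.
#' @param target_res target cell size in metres (default 100).
#' @return a `uls_stack` on the target grid.
#' @export
align_layers <- function(rasters, target_res = 100) {
  stopifnot(is.list(rasters), !is.null(names(rasters)))
  xmin <- max(vapply(rasters, `[[`, numeric(1), "xmin"))
  ymin <- max(vapply(rasters, `[[`, numeric(1), "ymin"))
  xmax <- min(vapply(rasters, raster_xmax, numeric(1)))
  ymax <- min(vapply(rasters, raster_ymax, numeric(1)))
  if (xmax <= xmin || ymax <= ymin)
    stop("input rasters do not overlap spatially", call. = FALSE)
  # snap the intersection outward-in to the target grid anchored at (xmin, ymin)
  nc_t <- floor((xmax - xmin) / target_res)
  nr_t <- floor((ymax - ymin) / target_res)
  if (nc_t < 1 || nr_t < 1) stop("overlap smaller than one target cell", call. = FALSE)

  out <- lapply(names(rasters), function(nm) {
    r <- rasters[[nm]]
    if (r$res <= target_res) {
      f <- target_res / r$res
      if (abs(f - round(f)) > 1e-9)
        stop("resolution of '", nm, "' is not an integer divisor of the target",
             call. = FALSE)
      f <- as.integer(round(f))
      # crop to the intersection first
      rc0 <- raster_cell(r, xmin + r$res / 2, ymin + nr_t * target_res - r$res / 2)
      rows <- rc0$row + seq_len(nr_t * f) - 1L
      cols <- rc0$col + seq_len(nc_t * f) - 1L
      m <- r$values[rows, cols, drop = FALSE]
      v <- if (f == 1L) m else block_aggregate(m, f, categorical = r$categorical)
    } else {
      if (!r$categorical)
        warning("layer '", nm, "' is coarser than the target grid; ",
                "nearest-neighbour upsampling", call. = FALSE)
      v <- matrix(raster_extract(
        r,
        rep(xmin + (seq_len(nc_t) - 0.5) * target_res, each = nr_t),
        rep(ymin + (nr_t - seq_len(nr_t) + 0.5) * target_res, times = nc_t)),
        nr_t, nc_t)
    }
    uls_raster(v, xmin, ymin, target_res,
               categorical = r$categorical, levels = r$levels)
  })
  names(out) <- names(rasters)
  uls_stack(out)
}

#' Screen continuous predictor layers for multicollinearity
#'
#' Extracts the continuous layers of a stack at observation points and
#' reports every pair whose absolute Pearson correlation exceeds the
#' threshold. An empty report is a pass.
#'
#' @param stack a `uls_stack`.
#' @param points data.frame with metric `x`, `y` columns (>= 10 rows).
#' @param threshold absolute correlation bound (default 0.7).
#' @return data.frame with columns `layer1`, `layer2`, `r`, one row per
#'   offending pair; layers whose extraction is entirely missing are listed
#'   in attribute `"unusable"`.
#' @export
check_multicollinearity <- function(stack, points, threshold = 0.7) {
  stopifnot(inherits(stack, "uls_stack"), nrow(points) >= 10)
  cont <- continuous_layers(stack)
  if (length(cont) < 2) stop("need at least 2 continuous layers", call. = FALSE)
  vals <- sapply(cont, function(nm)
    raster_extract(stack$layers[[nm]], points$x, points$y))
  unusable <- cont[colSums(!is.na(vals)) == 0]
  use <- setdiff(cont, unusable)
  rep <- data.frame(layer1 = character(), layer2 = character(), r = numeric())
  if (length(use) >= 2) {
    cm <- stats::cor(vals[, use, drop = FALSE],
                     use = "pairwise.complete.obs")
    for (i in seq_len(length(use) - 1)) for (j in (i + 1):length(use)) {
      if (!is.na(cm[i, j]) && abs(cm[i, j]) > threshold)
        rep <- rbind(rep, data.frame(layer1 = use[i], layer2 = use[j],
                                     r = cm[i, j]))
    }
  }
  attr(rep, "unusable") <- unusable
  rep
}
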