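#' Lightweight single-band raster grid
#'
#' The package works on regular metric grids (default 100 m resolution).
#' A `uls_raster` stores cell values as a matrix whose first row is the
#' northern edge of the grid; cell values refer to cell centres.
#'
#' @param values numeric or integer matrix; row 1 = northern edge.
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#' @param res cell size in metres (cells are square).
#' @param categorical logical; `TRUE` for coded categorical layers.
#' @param levels optional character vector naming the category codes
#'   (code `i` = `levels[i]`).
#' @return an object of class `uls_raster`.
#' @export
uls_raster <- function(values, xmin = 0, ymin = 0, res = 100,
                       categorical = FALSE, levels = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res,
         categorical = categorical, levels = levels),
    class = "uls_raster")
}

#' @export
print.uls_raster <- function(x, ...) {
  cat(sprintf("<uls_raster> %d x %d cells @ %g m, origin (%g, %g)%s\n",
              nrow(x$values), ncol(x$values), x$res, x$xmin, x$ymin,
              if (x$categorical) " [categorical]" else ""))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d NA\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.uls_raster <- function(x) dim(x$values)

raster_nrow <- function(r) nrow(r$values)
raster_ncol <- function(r) ncol(r$values)
raster_xmax <- function(r) r$xmin + raster_ncol(r) * r$res
raster_ymax <- function(r) r$ymin + raster_nrow(r) * r$res

#' Grid geometry of a raster
#'
#' @param r a `uls_raster`.
#' @return list with `nrow`, `ncol`, `xmin`, `ymin`, `res`.
#' @export
raster_grid <- function(r) {
  list(nrow = raster_nrow(r), ncol = raster_ncol(r),
       xmin = r$xmin, ymin = r$ymin, res = r$res)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(raster_grid(a)[c("nrow","ncol","xmin","ymin","res")],
                   raster_grid(b)[c("nrow","ncol","xmin","ymin","res")]))
}

#' Row/column index of the cells containing points
#'
#' Points on the grid edge are assigned to the adjacent interior cell so that
#' a trajectory touching the boundary still extracts a value.
#'
#' @param r a `uls_raster`.
#' @param x,y point coordinates (m), vectorised.
#' @return data.frame with integer columns `row`, `col`; NA outside the grid.
#' @export
raster_cell <- function(r, x, y) {
  col <- floor((x - r$xmin) / r$res) + 1L
  row <- raster_nrow(r) - floor((y - r$ymin) / r$res)
  col[x == raster_xmax(r)] <- raster_ncol(r)
  row[y == raster_ymax(r)] <- 1L
  bad <- x < r$xmin | x > raster_xmax(r) | y < r$ymin | y > raster_ymax(r) |
    is.na(x) | is.na(y)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations (nearest cell)
#'
#' @inheritParams raster_cell
#' @return vector of cell values; NA outside the grid.
#' @export
raster_extract <- function(r, x, y) {
  rc <- raster_cell(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- r$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Centre coordinates of every cell
#'
#' @param r a `uls_raster`.
#' @return data.frame with `row`, `col`, `x`, `y` for all cells in
#'   row-major order (row 1 = north).
#' @export
raster_coords <- function(r) {
  nr <- raster_nrow(r); nc <- raster_ncol(r)
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  data.frame(
    row = row, col = col,
    x = r$xmin + (col - 0.5) * r$res,
    y = r$ymin + (nr - row + 0.5) * r$res)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` format (NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE/
#' NODATA_VALUE header followed by rows north to south), readable by common
#' GIS software.
#'
#' @param r a `uls_raster`.
#' @param path output file path.
#' @param nodata value written for missing cells.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", raster_ncol(r)),
    sprintf("NROWS %d", raster_nrow(r)),
    sprintf("XLLCORNER %.6f", r$xmin),
    sprintf("YLLCORNER %.6f", r$ymin),
    sprintf("CELLSIZE %.6f", r$res),
    sprintf("NODATA_VALUE %g", nodata)), con)
  v <- r$values
  v[is.na(v)] <- nodata
  writeLines(apply(v, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file path.
#' @param categorical logical; mark the result categorical.
#' @param levels optional category names.
#' @return a `uls_raster`.
#' @export
read_ascii_grid <- function(path, categorical = FALSE, levels = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (grepl("^[A-Za-z]", lines[i + 1L])) {
    i <- i + 1L
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[toupper(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- scan(text = lines[-seq_len(i)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$NROWS, ncol = hdr$NCOLS, byrow = TRUE)
  if (!is.null(hdr$NODATA_VALUE)) m[m == hdr$NODATA_VALUE] <- NA
  uls_raster(m, xmin = hdr$XLLCORNER, ymin = hdr$YLLCORNER,
             res = hdr$CELLSIZE, categorical = categorical, levels = levels)
}
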