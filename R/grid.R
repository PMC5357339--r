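#' Equal-area grid geometry
#'
#' A `grid_spec` describes the shared geometry of every raster layer in an
#' analysis: cell counts, cell size (km) in an equal-area plane, the lower-left
#' corner of the extent, and a nodata mask marking invalid ("sea") cells.
#' Rows are ordered north to south (row 1 is the northernmost), columns west
#' to east. All layers on a grid are plain numeric matrices of dimension
#' `n_rows x n_cols` with `NA` on nodata cells.
#'
#' @param n_rows,n_cols cell counts (each >= 2).
#' @param cell_size_km cell edge length in km (> 0). Default 10.
#' @param origin_x,origin_y coordinates (km) of the lower-left corner of the
#'   extent in the equal-area plane. `origin_y` also anchors the latitude
#'   model: latitude (degrees) = y / 111.32.
#' @param nodata_mask logical `n_rows x n_cols` matrix, `TRUE` where cells are
#'   invalid. Default all valid.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_km = 10,
                      origin_x = 0, origin_y = 3500,
                      nodata_mask = NULL) {
  if (n_rows < 2 || n_cols < 2) stop("grid must have at least 2 rows and 2 columns")
  if (cell_size_km <= 0) stop("cell_size_km must be > 0")
  if (is.null(nodata_mask)) {
    nodata_mask <- matrix(FALSE, n_rows, n_cols)
  }
  nodata_mask <- as.matrix(nodata_mask)
  storage.mode(nodata_mask) <- "logical"
  if (!identical(dim(nodata_mask), c(as.integer(n_rows), as.integer(n_cols)))) {
    stop("nodata_mask dimensions must match n_rows x n_cols")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size_km = cell_size_km,
         origin_x = origin_x, origin_y = origin_y,
         nodata_mask = nodata_mask),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g km (%d nodata)\n",
              x$n_rows, x$n_cols, x$cell_size_km, sum(x$nodata_mask)))
  invisible(x)
}

grid_matches <- function(grid, values) {
  identical(dim(values), c(grid$n_rows, grid$n_cols))
}

stopifnot_layer <- function(grid, values, what = "layer") {
  if (!grid_matches(grid, values)) {
    stop(sprintf("%s dimensions (%s) do not match grid (%d x %d)",
                 what, paste(dim(values), collapse = " x "),
                 grid$n_rows, grid$n_cols))
  }
  invisible(TRUE)
}

#' Map plane coordinates to grid cells
#'
#' @param grid a [grid_spec()].
#' @param x,y coordinates (km) in the equal-area plane.
#' @return integer matrix with columns `row`, `col`; `NA` where the point
#'   falls outside the extent.
#' @export
cell_of_xy <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size_km) + 1
  row_from_bottom <- floor((y - grid$origin_y) / grid$cell_size_km) + 1
  row <- grid$n_rows - row_from_bottom + 1
  bad <- !is.finite(x) | !is.finite(y) |
    col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Cell centre coordinates
#' @param grid a [grid_spec()].
#' @param row,col cell indices (row 1 = north).
#' @return matrix with columns `x`, `y` (km).
#' @export
cell_center <- function(grid, row, col) {
  x <- grid$origin_x + (col - 0.5) * grid$cell_size_km
  y <- grid$origin_y + (grid$n_rows - row + 0.5) * grid$cell_size_km
  cbind(x = x, y = y)
}

# latitude (degrees) of each grid row's cell centres; simple equal-area
# plane -> degree conversion at 111.32 km per degree
lat_of_row <- function(grid, row) {
  y <- grid$origin_y + (grid$n_rows - row + 0.5) * grid$cell_size_km
  y / 111.32
}

#' Latitude layer for a grid
#' @param grid a [grid_spec()].
#' @return matrix of latitudes (degrees), `NA` on nodata cells.
#' @export
latitude_layer <- function(grid) {
  lat <- matrix(lat_of_row(grid, seq_len(grid$n_rows)),
                grid$n_rows, grid$n_cols)
  lat[grid$nodata_mask] <- NA_real_
  lat
}

#' Write / read a raster layer as ESRI ASCII grid
#'
#' Plain-text single-band raster exchange. Nodata cells (`NA`) are written as
#' -9999. `read_raster` reconstructs the `grid_spec` from the header and takes
#' the nodata mask from the nodata cells; values round-trip at full double
#' precision (written with `%.17g`).
#'
#' @param values numeric matrix on `grid`.
#' @param grid a [grid_spec()].
#' @param path file path (conventionally `.asc`).
#' @return `write_raster` returns `path` invisibly; `read_raster` returns
#'   `list(values, grid)`.
#' @export
write_raster <- function(values, grid, path) {
  stopifnot_layer(grid, values)
  v <- values
  v[grid$nodata_mask] <- NA_real_
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.17g", grid$origin_x),
    sprintf("yllcorner %.17g", grid$origin_y),
    sprintf("cellsize %.17g", grid$cell_size_km),
    "NODATA_value -9999"
  ), con)
  for (r in seq_len(grid$n_rows)) {
    row <- v[r, ]
    row_str <- ifelse(is.na(row), "-9999", sprintf("%.17g", row))
    writeLines(paste(row_str, collapse = " "), con)
  }
  invisible(path)
}

#' @param expected_grid optional [grid_spec()]; a mismatch in shape, cell size
#'   or origin is an error.
#' @rdname write_raster
#' @export
read_raster <- function(path, expected_grid = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  n_rows <- as.integer(hdr$nrows)
  n_cols <- as.integer(hdr$ncols)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != n_rows * n_cols) {
    stop("raster body does not match header dimensions")
  }
  m <- matrix(vals, n_rows, n_cols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid <- grid_spec(n_rows, n_cols, cell_size_km = hdr$cellsize,
                    origin_x = hdr$xllcorner, origin_y = hdr$yllcorner,
                    nodata_mask = is.na(m))
  if (!is.null(expected_grid)) {
    same <- grid$n_rows == expected_grid$n_rows &&
      grid$n_cols == expected_grid$n_cols &&
      isTRUE(all.equal(grid$cell_size_km, expected_grid$cell_size_km)) &&
      isTRUE(all.equal(grid$origin_x, expected_grid$origin_x)) &&
      isTRUE(all.equal(grid$origin_y, expected_grid$origin_y))
    if (!same) stop("raster grid does not match the expected grid_spec")
  }
  list(values = m, grid = grid)
}
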