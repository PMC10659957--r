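#' Lightweight gridded raster layer
#'
#' An in-memory raster: a numeric matrix on a regular lon/lat grid with a
#' square cell size in decimal degrees. Row 1 is the northernmost row
#' (map orientation); `NA` is the nodata value. This is the container every
#' gridded predictor (bioclimate layers, wind speed, population density,
#' suitability surfaces) travels in.
#'
#' @param values numeric matrix, row 1 = north.
#' @param xmin,ymin lower-left corner of the grid (degrees).
#' @param cellsize cell edge length in degrees (> 0).
#' @param name layer name.
#' @return an object of class `grid_layer`.
#' @export
grid_layer <- function(values, xmin, ymin, cellsize, name = "layer") {
  values <- as.matrix(values)
  stopifnot(is.numeric(cellsize), cellsize > 0, is.numeric(values))
  structure(
    list(
      name = name,
      values = values,
      xmin = xmin, ymin = ymin,
      cellsize = cellsize,
      nrow = nrow(values), ncol = ncol(values)
    ),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf(
    "<grid_layer '%s'> %d x %d cells, %.6g deg, extent [%.4f, %.4f] x [%.4f, %.4f]\n",
    x$name, x$nrow, x$ncol, x$cellsize,
    x$xmin, layer_xmax(x), x$ymin, layer_ymax(x)
  ))
  invisible(x)
}

layer_xmax <- function(layer) layer$xmin + layer$ncol * layer$cellsize
layer_ymax <- function(layer) layer$ymin + layer$nrow * layer$cellsize

#' Geographic extent
#'
#' @param min_lon,min_lat,max_lon,max_lat bounding coordinates in degrees;
#'   `min < max` on both axes. Membership is half-open: `[min, max)`.
#' @return an object of class `extent`.
#' @export
extent <- function(min_lon, min_lat, max_lon, max_lat) {
  if (!(min_lon < max_lon && min_lat < max_lat)) {
    stop("extent requires min < max on both axes", call. = FALSE)
  }
  structure(
    list(min_lon = min_lon, min_lat = min_lat,
         max_lon = max_lon, max_lat = max_lat),
    class = "extent"
  )
}

#' Extent of a grid layer
#' @param layer a `grid_layer`.
#' @return an `extent` covering the layer.
#' @export
layer_extent <- function(layer) {
  extent(layer$xmin, layer$ymin, layer_xmax(layer), layer_ymax(layer))
}

same_geometry <- function(a, b, tol = 1e-9) {
  abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol && a$nrow == b$nrow && a$ncol == b$ncol
}

#' Row/column of the cell containing each point
#'
#' Cells are half-open on their east and north edges so a point is in exactly
#' one cell. Points outside the grid get `NA` row/col.
#'
#' @param layer a `grid_layer`.
#' @param lon,lat point coordinates (degrees), recycled to common length.
#' @return data.frame with columns `row`, `col`, `cell` (1-based; `cell` is
#'   a single row-major index) — `NA` where the point is off-grid.
#' @export
cell_index <- function(layer, lon, lat) {
  col <- floor((lon - layer$xmin) / layer$cellsize) + 1L
  # half-open in both axes: lat = ymin is inside, lat = ymax is not
  row <- layer$nrow - floor((lat - layer$ymin) / layer$cellsize)
  bad <- col < 1L | col > layer$ncol | row < 1L | row > layer$nrow
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = row, col = col,
             cell = (row - 1L) * layer$ncol + col)
}

#' Center coordinates of cells
#' @param layer a `grid_layer`.
#' @param row,col cell indices (1-based, row 1 = north).
#' @return data.frame with `lon`, `lat` of cell centers.
#' @export
cell_center <- function(layer, row, col) {
  data.frame(
    lon = layer$xmin + (col - 0.5) * layer$cellsize,
    lat = layer_ymax(layer) - (row - 0.5) * layer$cellsize
  )
}

#' Value of the cell containing each point (nearest-cell lookup)
#' @param layer a `grid_layer`.
#' @param lon,lat point coordinates.
#' @return numeric vector; `NA` off-grid or on a nodata cell.
#' @export
layer_value_at <- function(layer, lon, lat) {
  idx <- cell_index(layer, lon, lat)
  out <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx$row)
  out[ok] <- layer$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Crop a layer to an extent
#'
#' Keeps all cells whose centers fall inside the (half-open) extent.
#'
#' @param layer a `grid_layer`.
#' @param ext an `extent`.
#' @return a `grid_layer`.
#' @export
crop_layer <- function(layer, ext) {
  cs <- layer$cellsize
  cols <- which(layer$xmin + (seq_len(layer$ncol) - 0.5) * cs >= ext$min_lon &
                  layer$xmin + (seq_len(layer$ncol) - 0.5) * cs < ext$max_lon)
  lats <- layer_ymax(layer) - (seq_len(layer$nrow) - 0.5) * cs
  rows <- which(lats >= ext$min_lat & lats < ext$max_lat)
  if (!length(rows) || !length(cols)) stop("crop produced an empty grid", call. = FALSE)
  grid_layer(layer$values[rows, cols, drop = FALSE],
             xmin = layer$xmin + (min(cols) - 1L) * cs,
             ymin = layer_ymax(layer) - max(rows) * cs,
             cellsize = cs, name = layer$name)
}

#' Read / write Esri ASCII grid files
#'
#' Plain-text raster interchange (`.asc`): a six-line header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by rows
#' of values, north first.
#'
#' @param path file path.
#' @param name layer name to attach on read.
#' @return `read_ascii_grid`: a `grid_layer`.
#' @export
read_ascii_grid <- function(path, name = sub("\\.asc$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  grid_layer(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
             cellsize = hdr$cellsize, name = name)
}

#' @rdname read_ascii_grid
#' @param layer a `grid_layer` to write.
#' @param nodata sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999) {
  m <- layer$values
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", layer$ncol),
    paste("nrows", layer$nrow),
    paste("xllcorner", format(layer$xmin, digits = 15)),
    paste("yllcorner", format(layer$ymin, digits = 15)),
    paste("cellsize", format(layer$cellsize, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Cell-wise mean of co-registered layers
#'
#' Used to build the equally weighted ensemble surface. Nodata in any input
#' propagates to the output.
#'
#' @param layers list of co-registered `grid_layer`s.
#' @param name output layer name.
#' @return a `grid_layer`.
#' @export
average_layers <- function(layers, name = "ensemble") {
  stopifnot(length(layers) >= 1)
  for (l in layers[-1]) {
    if (!same_geometry(layers[[1]], l)) {
      stop("layers are not co-registered", call. = FALSE)
    }
  }
  acc <- Reduce(`+`, lapply(layers, `[[`, "values"))
  grid_layer(acc / length(layers), layers[[1]]$xmin, layers[[1]]$ymin,
             layers[[1]]$cellsize, name = name)
}
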