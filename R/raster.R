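#' Planar grid rasters
#'
#' `popvuln` works on regular planar grids (projected coordinates in metres,
#' cell-centre registration, no geodesy). A `grid_raster` is a numeric matrix
#' whose first row is the northernmost row, together with the grid geometry:
#' lower-left corner, square cell size and a free-text CRS label. Missing data
#' are `NA` in memory and a numeric sentinel (default -9999) on disk.
#'
#' @param values numeric matrix; row 1 is the top (north) row.
#' @param xmin,ymin coordinates of the lower-left corner of the grid (m).
#' @param cellsize square cell edge length (m).
#' @param crs free-text label for the planar reference system.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, cellsize = 1, crs = "local-metres") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(nrow(values) >= 1, ncol(values) >= 1, cellsize > 0)
  structure(
    list(values = values,
         geom = grid_geometry(xmin, ymin, cellsize, nrow(values), ncol(values), crs)),
    class = "grid_raster"
  )
}

grid_geometry <- function(xmin, ymin, cellsize, n_rows, n_cols, crs = "local-metres") {
  list(xmin = xmin, ymin = ymin, cellsize = cellsize,
       n_rows = as.integer(n_rows), n_cols = as.integer(n_cols), crs = crs)
}

geom_equal <- function(a, b) {
  isTRUE(all.equal(a[c("xmin", "ymin", "cellsize")], b[c("xmin", "ymin", "cellsize")])) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' @export
print.grid_raster <- function(x, ...) {
  g <- x$geom
  cat(sprintf("<grid_raster> %d x %d cells, cellsize %g m, origin (%g, %g)\n",
              g$n_rows, g$n_cols, g$cellsize, g$xmin, g$ymin))
  v <- x$values[!is.na(x$values)]
  if (length(v)) cat(sprintf("  values: [%g, %g], %d NA\n", min(v), max(v),
                             sum(is.na(x$values))))
  invisible(x)
}

#' Locate points on a grid
#'
#' Maps planar coordinates to grid cells under the half-open cell convention
#' `[x0, x0 + cellsize)`: a point sitting exactly on the shared edge of two
#' cells belongs to the cell on the larger-coordinate side. Cell ids are
#' row-major, counted from the top-left cell.
#'
#' @param geom a grid geometry (or a `grid_raster` / `climate_stack`).
#' @param x,y point coordinates (m).
#' @return A tibble with columns `row`, `col`, `cell`; `NA` rows for points
#'   outside the grid.
#' @export
cell_index <- function(geom, x, y) {
  geom <- as_geometry(geom)
  stopifnot(length(x) == length(y))
  col <- floor((x - geom$xmin) / geom$cellsize) + 1
  row_from_bottom <- floor((y - geom$ymin) / geom$cellsize)
  row <- geom$n_rows - row_from_bottom
  bad <- col < 1 | col > geom$n_cols | row < 1 | row > geom$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col),
                 cell = as.integer((row - 1L) * geom$n_cols + col))
}

#' Cell centres of a grid
#'
#' @inheritParams cell_index
#' @return A tibble with one row per cell (row-major order): `cell`, `row`,
#'   `col`, `x`, `y`.
#' @export
cell_centers <- function(geom) {
  geom <- as_geometry(geom)
  ymax <- geom$ymin + geom$n_rows * geom$cellsize
  grid <- expand.grid(col = seq_len(geom$n_cols), row = seq_len(geom$n_rows))
  grid <- grid[order(grid$row, grid$col), ]
  tibble::tibble(
    cell = as.integer((grid$row - 1L) * geom$n_cols + grid$col),
    row = as.integer(grid$row), col = as.integer(grid$col),
    x = geom$xmin + (grid$col - 0.5) * geom$cellsize,
    y = ymax - (grid$row - 0.5) * geom$cellsize
  )
}

as_geometry <- function(x) {
  if (inherits(x, "grid_raster")) return(x$geom)
  if (inherits(x, "climate_stack")) return(x$geom)
  stopifnot(is.list(x), all(c("xmin", "ymin", "cellsize", "n_rows", "n_cols") %in% names(x)))
  x
}

# row-major vector of values (top-left cell first)
raster_values <- function(r) as.vector(t(r$values))

#' Write / read a grid as an ESRI ASCII grid
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values, north row first. Values are written with full double precision so a
#' write/read round trip is bit-identical.
#'
#' @param r a `grid_raster`.
#' @param path file path.
#' @param na_value numeric sentinel used for missing cells.
#' @return `read_ascii_grid` returns a `grid_raster`; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(r, path, na_value = -9999) {
  stopifnot(inherits(r, "grid_raster"))
  g <- r$geom
  v <- r$values
  if (any(v == na_value, na.rm = TRUE))
    stop("data contain the NODATA sentinel ", na_value, "; choose another")
  v[is.na(v)] <- na_value
  header <- c(
    paste("ncols", g$n_cols), paste("nrows", g$n_rows),
    paste("xllcorner", format(g$xmin, digits = 17)),
    paste("yllcorner", format(g$ymin, digits = 17)),
    paste("cellsize", format(g$cellsize, digits = 17)),
    paste("NODATA_value", format(na_value, digits = 17))
  )
  body <- apply(v, 1, function(row) paste(format(row, digits = 17, trim = TRUE,
                                                 scientific = FALSE), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param crs CRS label to attach on read (the format itself carries none).
#' @export
read_ascii_grid <- function(path, crs = "local-metres") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  body <- lines[-(1:6)]
  v <- t(vapply(strsplit(trimws(body), "\\s+"),
                function(s) as.numeric(s), numeric(vals[["ncols"]])))
  if (nrow(v) != vals[["nrows"]]) stop("row count mismatch in ", path)
  v[v == vals[["nodata_value"]]] <- NA
  grid_raster(v, xmin = vals[["xllcorner"]], ymin = vals[["yllcorner"]],
              cellsize = vals[["cellsize"]], crs = crs)
}

#' Climate predictor stacks
#'
#' A named set of co-registered predictor grids sharing one geometry. Layer
#' names are the predictor labels used throughout selection, model fitting and
#' projection.
#'
#' @param layers named list of numeric matrices (or `grid_raster`s) sharing
#'   one geometry.
#' @inheritParams grid_raster
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(layers, xmin = 0, ymin = 0, cellsize = 1, crs = "local-metres") {
  stopifnot(length(layers) >= 1)
  if (is.null(names(layers)) || anyDuplicated(names(layers)) || any(names(layers) == ""))
    stop("layers must have unique non-empty names")
  mats <- lapply(layers, function(l) {
    if (inherits(l, "grid_raster")) l$values else {m <- as.matrix(l); storage.mode(m) <- "double"; m}
  })
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all layers must share identical grid dimensions")
  if (inherits(layers[[1]], "grid_raster")) {
    g0 <- layers[[1]]$geom
    for (l in layers) if (inherits(l, "grid_raster") && !geom_equal(l$geom, g0))
      stop("layer geometry mismatch on stack assembly")
    xmin <- g0$xmin; ymin <- g0$ymin; cellsize <- g0$cellsize; crs <- g0$crs
  }
  structure(
    list(layers = mats,
         geom = grid_geometry(xmin, ymin, cellsize, dims[1, 1], dims[2, 1], crs)),
    class = "climate_stack"
  )
}

#' @export
print.climate_stack <- function(x, ...) {
  g <- x$geom
  cat(sprintf("<climate_stack> %d layers on %d x %d grid (cellsize %g m)\n",
              length(x$layers), g$n_rows, g$n_cols, g$cellsize))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Stack values as a cells-by-predictors matrix
#'
#' @param stack a `climate_stack`.
#' @return Numeric matrix, one row per cell in row-major order, one column per
#'   layer.
#' @export
stack_values <- function(stack) {
  stopifnot(inherits(stack, "climate_stack"))
  m <- vapply(stack$layers, function(v) as.vector(t(v)),
              numeric(stack$geom$n_rows * stack$geom$n_cols))
  colnames(m) <- names(stack$layers)
  m
}

# pull one layer as grid_raster
stack_layer <- function(stack, name) {
  if (!name %in% names(stack$layers)) stop("unknown layer: ", name)
  g <- stack$geom
  grid_raster(stack$layers[[name]], g$xmin, g$ymin, g$cellsize, g$crs)
}
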