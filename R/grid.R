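#' Define an equal-area analysis grid
#'
#' All layers in a study share one planar, equal-area pixel lattice. Rows run
#' north to south (row 1 is the northernmost), columns west to east. Pixel
#' area is `pixel_size_km^2` everywhere, mirroring the ~100 km2 equal-area
#' cells used in global conservation grids.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param pixel_size_km Side length of a square pixel in kilometres.
#' @param origin_x_km,origin_y_km Planar coordinates (km) of the north-west
#'   corner of the grid.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, pixel_size_km = 10,
                      origin_x_km = 0, origin_y_km = 0) {
  stopifnot(n_rows >= 1, n_cols >= 1, pixel_size_km > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_size_km = pixel_size_km,
         origin_x_km = origin_x_km, origin_y_km = origin_y_km),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, %.3g km pixels (%.5g km2 each)\n",
              x$n_rows, x$n_cols, x$pixel_size_km, pixel_area_km2(x)))
  invisible(x)
}

#' Pixel area of a grid
#' @param grid A `grid_spec`.
#' @return Area of one pixel in km2.
#' @export
pixel_area_km2 <- function(grid) grid$pixel_size_km^2

#' Planar coordinates of pixel centers
#'
#' @param grid A `grid_spec`.
#' @return A list with `x` (length `n_cols`, west to east) and `y`
#'   (length `n_rows`, north to south) center coordinates in km.
#' @export
pixel_centers <- function(grid) {
  ps <- grid$pixel_size_km
  list(x = grid$origin_x_km + (seq_len(grid$n_cols) - 0.5) * ps,
       y = grid$origin_y_km - (seq_len(grid$n_rows) - 0.5) * ps)
}

#' Construct a boolean raster on a grid
#'
#' @param values Logical matrix of dimension `n_rows x n_cols` (row 1 north),
#'   or a single logical recycled to the full grid.
#' @param grid A `grid_spec`.
#' @return An object of class `bool_raster`: a logical matrix with the grid
#'   attached as attribute `grid`.
#' @export
bool_raster <- function(values, grid) {
  if (length(values) == 1L)
    values <- matrix(as.logical(values), grid$n_rows, grid$n_cols)
  values <- as.matrix(values)
  stopifnot(is.logical(values),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  structure(values, grid = grid, class = c("bool_raster", "matrix", "array"))
}

#' @export
print.bool_raster <- function(x, ...) {
  g <- raster_grid(x)
  cat(sprintf("<bool_raster> %d x %d, %d TRUE (%.5g km2)\n",
              g$n_rows, g$n_cols, sum(x), area_km2(x)))
  invisible(x)
}

#' Grid of a raster layer
#' @param x A raster-like object carrying a `grid` attribute.
#' @return The `grid_spec` the layer lives on.
#' @export
raster_grid <- function(x) attr(x, "grid", exact = TRUE)

same_grid <- function(a, b) {
  identical(unclass(raster_grid(a)), unclass(raster_grid(b)))
}

assert_same_grid <- function(...) {
  layers <- list(...)
  for (i in seq_along(layers)[-1])
    if (!same_grid(layers[[1]], layers[[i]]))
      stop("layers do not share one grid_spec", call. = FALSE)
  invisible(TRUE)
}

#' Construct a planar polygon
#'
#' Polygons live in the grid's planar km coordinates. The exterior ring may be
#' given open or closed; it is stored open (first vertex not repeated). Holes
#' are optional inner rings.
#'
#' @param exterior Two-column numeric matrix of (x, y) vertices in km.
#' @param holes Optional list of two-column matrices, one per hole.
#' @return An object of class `planar_polygon`.
#' @export
planar_polygon <- function(exterior, holes = list()) {
  close_ring <- function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 2)
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  exterior <- close_ring(exterior)
  if (nrow(exterior) < 3L)
    stop("degenerate polygon: fewer than 3 distinct vertices", call. = FALSE)
  if (abs(ring_area(exterior)) <= 0)
    stop("degenerate polygon: zero area", call. = FALSE)
  holes <- lapply(holes, close_ring)
  structure(list(exterior = exterior, holes = holes), class = "planar_polygon")
}

# shoelace signed area of an open ring
ring_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Planar area of a polygon (km2)
#' @param poly A `planar_polygon`.
#' @return Exterior area minus hole areas, in km2.
#' @export
polygon_area_km2 <- function(poly) {
  a <- abs(ring_area(poly$exterior))
  if (length(poly$holes))
    a <- a - sum(vapply(poly$holes, function(h) abs(ring_area(h)), numeric(1)))
  a
}

#' Rasterize a polygon by pixel-center containment
#'
#' A pixel is TRUE iff its center point falls strictly inside the polygon
#' (and inside no hole). Centers exactly on a ring are excluded. This
#' center-containment dialect matches the default vector-to-raster behaviour
#' of common GIS toolchains and is fixed so that all downstream area counts
#' are reproducible.
#'
#' @param poly A `planar_polygon` in the grid's km coordinates.
#' @param grid A `grid_spec`.
#' @return A `bool_raster`.
#' @export
rasterize_polygon <- function(poly, grid) {
  if (!inherits(poly, "planar_polygon")) stop("poly must be a planar_polygon")
  ctr <- pixel_centers(grid)
  out <- matrix(FALSE, grid$n_rows, grid$n_cols)

  # restrict the center test to the polygon's bounding box
  bx <- range(poly$exterior[, 1]); by <- range(poly$exterior[, 2])
  cols <- which(ctr$x >= bx[1] & ctr$x <= bx[2])
  rows <- which(ctr$y >= by[1] & ctr$y <= by[2])
  if (!length(cols) || !length(rows)) return(bool_raster(out, grid))

  px <- rep(ctr$x[cols], each = length(rows))
  py <- rep(ctr$y[rows], times = length(cols))
  inside <- pracma::inpolygon(px, py, poly$exterior[, 1], poly$exterior[, 2],
                              boundary = FALSE)
  for (h in poly$holes)
    inside <- inside & !pracma::inpolygon(px, py, h[, 1], h[, 2],
                                          boundary = TRUE)
  out[rows, cols] <- matrix(inside, length(rows), length(cols))
  bool_raster(out, grid)
}

#' Area covered by a mask
#' @param mask A `bool_raster`.
#' @return TRUE-pixel count times the pixel area, in km2.
#' @export
area_km2 <- function(mask) sum(mask) * pixel_area_km2(raster_grid(mask))

#' Dilate a mask by one pixel (Moore neighbourhood)
#'
#' Every pixel within Chebyshev distance 1 of a TRUE pixel becomes TRUE; at a
#' grid side length of ~10 km this realizes a "within 10 km of the boundary"
#' band. Grid edges clamp (no wraparound).
#'
#' @param mask A `bool_raster`.
#' @return The dilated `bool_raster`.
#' @export
dilate_one_pixel <- function(mask) {
  g <- raster_grid(mask)
  m <- unclass(mask); attr(m, "grid") <- NULL
  nr <- nrow(m); nc <- ncol(m)
  # separable: a 3x3 Moore dilation is a vertical then horizontal 1-D dilation
  v <- m
  if (nr > 1L) {
    v[-nr, ] <- v[-nr, ] | m[-1L, ]
    v[-1L, ] <- v[-1L, ] | m[-nr, ]
  }
  acc <- v
  if (nc > 1L) {
    acc[, -nc] <- acc[, -nc] | v[, -1L]
    acc[, -1L] <- acc[, -1L] | v[, -nc]
  }
  bool_raster(acc, g)
}

# ---- plain-text raster interchange (ESRI ASCII grid) -----------------------

#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange readable by standard GIS tools.
#' Logical layers are written as 0/1; missing values as the nodata code.
#'
#' @param x A `bool_raster` or a numeric matrix with a `grid` attribute.
#' @param path Output file path.
#' @param nodata Nodata code written for `NA` cells.
#' @export
write_ascii_raster <- function(x, path, nodata = -9999) {
  g <- raster_grid(x)
  if (is.null(g)) stop("x carries no grid_spec")
  m <- unclass(x)
  storage.mode(m) <- "double"
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$origin_x_km),
           sprintf("yllcorner %.10g", g$origin_y_km - g$n_rows * g$pixel_size_km),
           sprintf("cellsize %.10g", g$pixel_size_km),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_raster()] or any conforming tool.
#' @param logical If TRUE return a `bool_raster` (nonzero = TRUE); otherwise a
#'   numeric matrix with the grid attached and nodata cells set to `NA`.
#' @return A `bool_raster` or numeric grid matrix.
#' @export
read_ascii_raster <- function(path, logical = FALSE) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows"); cell <- val("cellsize")
  xll <- val("xllcorner"); yll <- val("yllcorner"); nodata <- val("NODATA_value")
  g <- grid_spec(nr, nc, cell, origin_x_km = xll,
                 origin_y_km = yll + nr * cell)
  m <- do.call(rbind, lapply(lines[-(1:6)], function(ln)
    as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])))
  m[m == nodata] <- NA
  if (logical) return(bool_raster(!is.na(m) & m != 0, g))
  structure(m, grid = g)
}

#' Attach a grid to a numeric matrix layer
#' @param values Numeric matrix (`n_rows x n_cols`).
#' @param grid A `grid_spec`.
#' @return The matrix with the grid as attribute, class `grid_layer`.
#' @export
grid_layer <- function(values, grid) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  structure(values, grid = grid, class = c("grid_layer", "matrix", "array"))
}
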