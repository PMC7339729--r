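#' Define a regular analysis grid
#'
#' The model operates on a regular grid of square cells (the native
#' resolution of the gridded CTM output, e.g. 12 x 12 km). Coordinates are
#' planar km; cell `(0, 0)` is the lower-left cell and the centroid of cell
#' `(i, j)` is `(x0 + i * cell_size, y0 + j * cell_size)`.
#'
#' @param nx,ny Number of cells in x and y (>= 1).
#' @param cell_size Cell edge length in km (> 0).
#' @param origin Numeric length-2: `(x0, y0)` km of the lower-left cell
#'   centroid.
#' @return A `ds_grid` object.
#' @examples
#' g <- make_grid(30, 30, cell_size = 12)
#' grid_centroids(g)
#' @export
make_grid <- function(nx, ny, cell_size = 12, origin = c(0, 0)) {
  stopifnot(length(nx) == 1, length(ny) == 1, length(cell_size) == 1,
            length(origin) == 2)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 1L || ny < 1L)
    stop("grid dimensions must be integers >= 1", call. = FALSE)
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be > 0", call. = FALSE)
  structure(
    list(nx = nx, ny = ny, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "ds_grid"
  )
}

#' @export
print.ds_grid <- function(x, ...) {
  cat(sprintf("<ds_grid> %d x %d cells, %.3g km cells, origin (%.4g, %.4g) km\n",
              x$nx, x$ny, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Grid cell centroids
#'
#' @param grid A `ds_grid`.
#' @return Tibble with 0-based cell indices `cell_x`, `cell_y` and centroid
#'   coordinates `x`, `y` in km, ordered row-major with `cell_x` fastest.
#' @export
grid_centroids <- function(grid) {
  stopifnot(inherits(grid, "ds_grid"))
  idx <- expand.grid(cell_x = 0:(grid$nx - 1L), cell_y = 0:(grid$ny - 1L))
  tibble::tibble(
    cell_x = as.integer(idx$cell_x),
    cell_y = as.integer(idx$cell_y),
    x = grid$origin[1] + idx$cell_x * grid$cell_size,
    y = grid$origin[2] + idx$cell_y * grid$cell_size
  )
}

#' Number of cells in a grid
#' @param grid A `ds_grid`.
#' @return Integer cell count.
#' @export
n_cells <- function(grid) grid$nx * grid$ny

# Bounding box of cell EDGES: points within half a cell of the outermost
# centroids are inside the gridded domain.
grid_extent <- function(grid) {
  h <- grid$cell_size / 2
  list(
    xmin = grid$origin[1] - h,
    xmax = grid$origin[1] + (grid$nx - 1L) * grid$cell_size + h,
    ymin = grid$origin[2] - h,
    ymax = grid$origin[2] + (grid$ny - 1L) * grid$cell_size + h
  )
}

in_grid <- function(grid, x, y) {
  e <- grid_extent(grid)
  x >= e$xmin & x <= e$xmax & y >= e$ymin & y <= e$ymax
}

# 0-based cell index containing a point (clamped to the domain edge)
containing_cell <- function(grid, x, y) {
  cx <- pmin(pmax(as.integer(round((x - grid$origin[1]) / grid$cell_size)), 0L),
             grid$nx - 1L)
  cy <- pmin(pmax(as.integer(round((y - grid$origin[2]) / grid$cell_size)), 0L),
             grid$ny - 1L)
  list(cell_x = cx, cell_y = cy)
}
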