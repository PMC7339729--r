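#' Exponential kernel weights over neighbouring grid cells
#'
#' For a point location the weighted CTM regressor uses the grid cell
#' containing the point plus up to three neighbouring cells in each axis
#' direction (a window of at most 7 x 7 = 49 cells, truncated at domain
#' edges). Weights decay exponentially with centroid distance,
#' `w_i` proportional to `exp(-kernel_decay * d_i)`, and are normalized to
#' sum to one.
#'
#' @param x,y Point coordinates in km (inside the grid extent).
#' @param grid A [make_grid()] grid.
#' @param kernel_decay Decay rate in 1/km (> 0).
#' @return Tibble with `cell_x`, `cell_y`, `dist_km`, `weight`.
#' @export
kernel_weights <- function(x, y, grid, kernel_decay) {
  stopifnot(inherits(grid, "ds_grid"), length(x) == 1, length(y) == 1)
  if (!is.finite(kernel_decay) || kernel_decay <= 0)
    stop("kernel_decay must be > 0", call. = FALSE)
  if (!in_grid(grid, x, y))
    stop("site (", x, ", ", y, ") lies outside the grid extent", call. = FALSE)
  cc <- containing_cell(grid, x, y)
  cxs <- max(0L, cc$cell_x - 3L):min(grid$nx - 1L, cc$cell_x + 3L)
  cys <- max(0L, cc$cell_y - 3L):min(grid$ny - 1L, cc$cell_y + 3L)
  w <- expand.grid(cell_x = cxs, cell_y = cys)
  d <- sqrt((grid$origin[1] + w$cell_x * grid$cell_size - x)^2 +
            (grid$origin[2] + w$cell_y * grid$cell_size - y)^2)
  # subtract min distance before exponentiating for numerical safety at
  # large decay; normalization cancels the shift
  lw <- -kernel_decay * (d - min(d))
  wt <- exp(lw) / sum(exp(lw))
  tibble::tibble(cell_x = as.integer(w$cell_x), cell_y = as.integer(w$cell_y),
                 dist_km = d, weight = wt)
}

#' Kernel-weighted CTM regressor at a point
#'
#' Computes `x~(s)`, the kernel-weighted average of the gridded CTM values
#' over the cell containing `s` and its neighbours (see [kernel_weights()]).
#'
#' @param x,y Point coordinates in km.
#' @param ctm_values Numeric vector of the day's CTM values ordered as
#'   [grid_centroids()].
#' @param grid The grid.
#' @param kernel_decay Decay in 1/km.
#' @return The scalar weighted regressor value.
#' @export
build_weighted_regressor <- function(x, y, ctm_values, grid, kernel_decay) {
  kw <- kernel_weights(x, y, grid, kernel_decay)
  idx <- kw$cell_y * grid$nx + kw$cell_x + 1L
  sum(kw$weight * ctm_values[idx])
}

# Regressor values for many sites and many candidate decays at once.
# coords: n x 2 matrix; returns n x length(decays) matrix.
regressor_matrix <- function(coords, ctm_values, grid, decays) {
  n <- nrow(coords)
  out <- matrix(NA_real_, n, length(decays))
  for (i in seq_len(n)) {
    for (k in seq_along(decays)) {
      out[i, k] <- build_weighted_regressor(coords[i, 1], coords[i, 2],
                                            ctm_values, grid, decays[k])
    }
  }
  out
}

#' Candidate GP range parameters from inter-site distances
#'
#' The spatial decay (range) parameter of the local-intercept Gaussian
#' process is estimated by a grid search placing discrete uniform prior mass
#' on fractions of the maximum pairwise inter-site distance.
#'
#' @param sites Site tibble with `x`, `y` columns (>= 2 distinct locations).
#' @param fracs Fractions in (0, 1] of the maximum pairwise distance.
#' @return Numeric vector of candidate ranges (km).
#' @export
decay_candidates <- function(sites, fracs = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.5)) {
  stopifnot(all(fracs > 0), all(fracs <= 1))
  if (nrow(sites) < 2) stop("need >= 2 sites", call. = FALSE)
  dmax <- max(pair_dist(cbind(sites$x, sites$y)))
  if (dmax <= 0)
    stop("all sites share one location; max inter-site distance is 0",
         call. = FALSE)
  fracs * dmax
}
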