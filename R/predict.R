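# Kernel-weighted regressor evaluated at every grid centroid at once.
# For a point at a centroid the <=7x7 window weights depend only on the
# (dx, dy) offset, so the field is accumulated by shifted-matrix sums with
# edge truncation and renormalization.
centroid_regressor <- function(grid, ctm_values, kernel_decay) {
  nx <- grid$nx; ny <- grid$ny
  M <- matrix(ctm_values, nrow = nx, ncol = ny)
  num <- matrix(0, nx, ny); den <- matrix(0, nx, ny)
  for (dx in -3:3) for (dy in -3:3) {
    wgt <- exp(-kernel_decay * grid$cell_size * sqrt(dx^2 + dy^2))
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    num[xs, ys] <- num[xs, ys] + wgt * M[xs + dx, ys + dy]
    den[xs, ys] <- den[xs, ys] + wgt
  }
  as.numeric(num / den)
}

#' Predict the concentration surface for one fitted day
#'
#' For every retained posterior draw the local intercept is extended from
#' the fitted sites to each grid centroid by its Gaussian-process
#' conditional distribution, and the noise-free surface
#' `beta0 + beta0(g) + beta1 * x~(g)` is formed with the draw's kernel
#' decay. The per-cell posterior mean and standard deviation of that
#' surface are reported as the prediction and its standard error (the
#' standard error excludes the measurement-error variance `sigma2`).
#'
#' @param fit A [fit_day()] result.
#' @param ctm Gridded field tibble covering the fitted date.
#' @param grid The grid.
#' @param seed Seed for the conditional-draw noise; defaults to a value
#'   derived from the fit's own seed so prediction is reproducible.
#' @return A `ds_surface` tibble: `date, cell_x, cell_y, x, y, pm25_mean,
#'   pm25_se`.
#' @export
predict_day <- function(fit, ctm, grid, seed = day_seed(fit$seed, 1L)) {
  stopifnot(inherits(fit, "ds_fit"))
  cent <- grid_centroids(grid)
  nc <- nrow(cent)
  v <- field_day_values(ctm, grid, fit$date)
  XT <- vapply(fit$kernel_decay_grid, function(kd)
    centroid_regressor(grid, v, kd), numeric(nc))   # nc x K

  d <- fit$draws
  nd <- length(d$beta0)
  S <- matrix(NA_real_, nd, nc)
  site_xy <- cbind(fit$sites$x, fit$sites$y)
  tgt_xy <- cbind(cent$x, cent$y)
  with_seed(seed, {
    for (j in sort(unique(d$rho_idx))) {
      rows <- which(d$rho_idx == j)
      cond <- gp_conditional(site_xy, tgt_xy,
                             d$w[rows, , drop = FALSE],
                             d$tau2[rows], fit$rho_candidates[j])
      z <- matrix(stats::rnorm(length(rows) * nc), length(rows), nc)
      S[rows, ] <- cond$mean + sqrt(cond$var) * z
    }
    invisible(NULL)
  })
  S <- S + d$beta0 + d$beta1 * t(XT[, d$decay_idx, drop = FALSE])
  m <- colMeans(S)
  se <- sqrt(pmax(colMeans(S * S) - m^2, 0) * nd / max(nd - 1, 1))
  out <- tibble::tibble(date = fit$date, cell_x = cent$cell_x,
                        cell_y = cent$cell_y, x = cent$x, y = cent$y,
                        pm25_mean = m, pm25_se = se)
  class(out) <- c("ds_surface", class(out))
  out
}

#' Posterior predictive distribution at point locations
#'
#' Used for cross-validation of withheld observations: draws the local
#' intercept at each target point conditionally on the fitted sites, forms
#' the surface value for every retained draw, and (by default) adds the
#' observation noise `eps ~ N(0, sigma2)` so the interval is a predictive
#' interval for a new observation.
#'
#' @param fit A [fit_day()] result.
#' @param points Tibble/data frame with `x`, `y` columns (km).
#' @param ctm Gridded field tibble covering the fitted date.
#' @param grid The grid.
#' @param include_noise Add measurement-error noise to the draws
#'   (predictive interval) or not (surface interval).
#' @param level Central interval probability.
#' @param seed RNG seed for the conditional draws.
#' @return Tibble with `x, y, pred_mean, pred_se, pred_lo, pred_hi`.
#' @export
predict_points <- function(fit, points, ctm, grid, include_noise = TRUE,
                           level = 0.95, seed = day_seed(fit$seed, 2L)) {
  stopifnot(inherits(fit, "ds_fit"))
  m <- nrow(points)
  v <- field_day_values(ctm, grid, fit$date)
  xt <- vapply(fit$kernel_decay_grid, function(kd)
    vapply(seq_len(m), function(i)
      build_weighted_regressor(points$x[i], points$y[i], v, grid, kd),
      numeric(1)), numeric(m))
  xt <- matrix(xt, nrow = m)                      # m x K

  d <- fit$draws
  nd <- length(d$beta0)
  S <- matrix(NA_real_, nd, m)
  site_xy <- cbind(fit$sites$x, fit$sites$y)
  with_seed(seed, {
    for (j in sort(unique(d$rho_idx))) {
      rows <- which(d$rho_idx == j)
      cond <- gp_conditional(site_xy, cbind(points$x, points$y),
                             d$w[rows, , drop = FALSE],
                             d$tau2[rows], fit$rho_candidates[j])
      z <- matrix(stats::rnorm(length(rows) * m), length(rows), m)
      S[rows, ] <- cond$mean + sqrt(cond$var) * z
    }
    S <- S + d$beta0 + d$beta1 * t(xt[, d$decay_idx, drop = FALSE])
    if (include_noise)
      S <- S + matrix(stats::rnorm(nd * m, sd = sqrt(d$sigma2)), nd, m)
    invisible(NULL)
  })
  a <- (1 - level) / 2
  qs <- apply(S, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  tibble::tibble(
    x = points$x, y = points$y,
    pred_mean = colMeans(S),
    pred_se = apply(S, 2, stats::sd),
    pred_lo = qs[1, ], pred_hi = qs[2, ])
}
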