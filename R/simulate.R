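#' Simulate a gridded daily concentration field (CTM surrogate)
#'
#' Builds a smooth daily PM2.5 field standing in for chemical transport
#' model (CTM) output: a constant regional background, isotropic Gaussian
#' "hotspot" bumps representing urban plumes, and a spatially correlated
#' daily anomaly with exponential covariance. Values are clipped at zero.
#'
#' @param grid A [make_grid()] grid.
#' @param dates Vector of `Date`s (strictly increasing).
#' @param base_level Background concentration, ug/m3 (>= 0).
#' @param hotspots Tibble/data frame with columns `x`, `y` (km),
#'   `amplitude` (ug/m3) and `width` (km, Gaussian sd); may have 0 rows.
#' @param day_sd Standard deviation of the daily spatial anomaly (ug/m3).
#' @param range_km Exponential correlation range of the anomaly (km).
#' @param seed Integer seed; the field is a pure function of (inputs, seed).
#' @return Tibble `date, cell_x, cell_y, x, y, pm25` (one row per day-cell).
#' @examples
#' g <- make_grid(10, 10, 12)
#' f <- simulate_ctm_field(g, as.Date("2014-01-01") + 0:4, seed = 1)
#' @export
simulate_ctm_field <- function(grid, dates, base_level = 8,
                               hotspots = default_hotspots(grid),
                               day_sd = 2, range_km = 60, seed) {
  stopifnot(inherits(grid, "ds_grid"))
  dates <- as.Date(dates)
  if (length(dates) == 0) stop("dates must be non-empty", call. = FALSE)
  if (any(diff(dates) <= 0)) stop("dates must be strictly increasing", call. = FALSE)
  if (!is.finite(base_level) || base_level < 0)
    stop("base_level must be >= 0", call. = FALSE)
  cent <- grid_centroids(grid)
  static <- rep(base_level, nrow(cent))
  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    for (k in seq_len(nrow(hotspots))) {
      d2 <- (cent$x - hotspots$x[k])^2 + (cent$y - hotspots$y[k])^2
      static <- static + hotspots$amplitude[k] * exp(-d2 / (2 * hotspots$width[k]^2))
    }
  }
  nc <- nrow(cent)
  anom <- matrix(0, length(dates), nc)
  if (day_sd > 0) {
    L <- chol(exp_corr(pair_dist(cbind(cent$x, cent$y)), range_km) +
              diag(1e-10, nc))
    anom <- with_seed(seed, {
      z <- matrix(stats::rnorm(length(dates) * nc), length(dates), nc)
      day_sd * z %*% L
    })
  }
  vals <- sweep(anom, 2, static, "+")
  vals[vals < 0] <- 0
  tibble::tibble(
    date = rep(dates, each = nc),
    cell_x = rep(cent$cell_x, length(dates)),
    cell_y = rep(cent$cell_y, length(dates)),
    x = rep(cent$x, length(dates)),
    y = rep(cent$y, length(dates)),
    pm25 = as.numeric(t(vals))
  )
}

#' Default hotspot layout for a grid
#'
#' Two urban plumes: a stronger one in the interior and a weaker one offset
#' towards a corner, scaled to the grid extent.
#'
#' @param grid A grid.
#' @return Tibble with `x`, `y`, `amplitude`, `width`.
#' @export
default_hotspots <- function(grid) {
  e <- grid_extent(grid)
  wx <- e$xmax - e$xmin; wy <- e$ymax - e$ymin
  tibble::tibble(
    x = e$xmin + c(0.35, 0.75) * wx,
    y = e$ymin + c(0.40, 0.70) * wy,
    amplitude = c(8, 5),
    width = c(0.12, 0.08) * max(wx, wy)
  )
}

#' Place urban and remote monitoring sites
#'
#' Urban sites are placed preferentially near hotspots (sampling cells with
#' probability proportional to the hotspot surface plus a small floor);
#' remote sites are placed preferentially in low-concentration regions.
#' Each site gets a uniform jitter within its cell. This mimics a
#' regulatory network concentrated in populated, polluted areas and a
#' remote-area network filling the spatial gaps.
#'
#' @param grid A grid.
#' @param n_urban,n_remote Site counts (total >= 1, at most one site per
#'   cell).
#' @param hotspots Hotspot tibble as in [simulate_ctm_field()].
#' @param seed Integer seed.
#' @return Site tibble: `site_id`, `x`, `y` (km), `network`
#'   (`"urban"`/`"remote"`).
#' @export
place_monitors <- function(grid, n_urban, n_remote,
                           hotspots = default_hotspots(grid), seed) {
  stopifnot(inherits(grid, "ds_grid"))
  n_urban <- as.integer(n_urban); n_remote <- as.integer(n_remote)
  if (n_urban < 0 || n_remote < 0 || n_urban + n_remote < 1)
    stop("need n_urban + n_remote >= 1", call. = FALSE)
  if (n_urban + n_remote > n_cells(grid))
    stop("more sites requested than distinct grid cells", call. = FALSE)
  cent <- grid_centroids(grid)
  hs <- rep(0, nrow(cent))
  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    for (k in seq_len(nrow(hotspots))) {
      d2 <- (cent$x - hotspots$x[k])^2 + (cent$y - hotspots$y[k])^2
      hs <- hs + hotspots$amplitude[k] * exp(-d2 / (2 * hotspots$width[k]^2))
    }
  }
  with_seed(seed, {
    p_urban <- hs + 0.02 * max(hs, 1)
    p_remote <- max(hs) - hs + 0.02 * max(hs, 1)
    iu <- if (n_urban > 0)
      sample.int(nrow(cent), n_urban, prob = p_urban) else integer(0)
    avail <- setdiff(seq_len(nrow(cent)), iu)
    ir <- if (n_remote > 0)
      avail[sample.int(length(avail), n_remote,
                       prob = p_remote[avail])] else integer(0)
    idx <- c(iu, ir)
    jit <- matrix(stats::runif(2 * length(idx), -0.45, 0.45) * grid$cell_size,
                  ncol = 2)
    tibble::tibble(
      site_id = c(sprintf("U%03d", seq_len(n_urban)),
                  sprintf("R%03d", seq_len(n_remote))),
      x = cent$x[idx] + jit[, 1],
      y = cent$y[idx] + jit[, 2],
      network = rep(c("urban", "remote"), c(n_urban, n_remote))
    )
  })
}

#' Assign sampling schedules to monitoring sites
#'
#' Urban sites are assigned multinomially to 1-in-6-day, 1-in-3-day, or
#' daily sampling (defaults reflect the roughly 13% / 47% / 40% mix of a
#' regulatory PM2.5 network), each with its own random schedule offset.
#' All remote sites share a single common 1-in-3-day offset, matching the
#' shared national schedule of remote visibility-network samplers.
#'
#' @param sites Site tibble from [place_monitors()].
#' @param urban_fracs Length-3 nonnegative fractions (1-in-6, 1-in-3,
#'   daily) summing to 1.
#' @param seed Integer seed.
#' @return `sites` with `schedule` (`"one_in_six"`, `"one_in_three"`,
#'   `"daily"`) and integer `offset` columns (offset 0 for daily sites).
#' @export
assign_schedules <- function(sites, urban_fracs = c(0.13, 0.47, 0.40), seed) {
  stopifnot(length(urban_fracs) == 3)
  if (any(urban_fracs < 0)) stop("fractions must be nonnegative", call. = FALSE)
  if (abs(sum(urban_fracs) - 1) > 1e-8)
    stop("urban_fracs must sum to 1", call. = FALSE)
  with_seed(seed, {
    sched <- rep("one_in_three", nrow(sites))
    offset <- integer(nrow(sites))
    iu <- which(sites$network == "urban")
    if (length(iu) > 0) {
      pick <- sample(c("one_in_six", "one_in_three", "daily"), length(iu),
                     replace = TRUE, prob = urban_fracs)
      sched[iu] <- pick
      offset[iu] <- ifelse(pick == "one_in_six",
                           sample.int(6, length(iu), replace = TRUE) - 1L,
                    ifelse(pick == "one_in_three",
                           sample.int(3, length(iu), replace = TRUE) - 1L, 0L))
    }
    ir <- which(sites$network == "remote")
    if (length(ir) > 0) {
      shared <- sample.int(3, 1) - 1L
      sched[ir] <- "one_in_three"
      offset[ir] <- shared
    }
    dplyr::mutate(sites, schedule = sched, offset = as.integer(offset))
  })
}

# Dates on which a site reports, given its schedule and the period's first
# date (day index 0). Offsets are day-index residues.
scheduled_dates <- function(schedule, offset, dates, origin_date = min(dates)) {
  di <- day_index(dates, origin_date)
  switch(schedule,
    daily = dates,
    one_in_three = dates[di %% 3L == offset %% 3L],
    one_in_six = dates[di %% 6L == offset %% 6L],
    stop("unknown schedule: ", schedule, call. = FALSE)
  )
}

#' Simulate monitor observations from the Downscaler generative model
#'
#' For every scheduled site-day, draws
#' `Y(s) = beta0 + beta0(s) + beta1 * x~(s) + eps`, where `x~(s)` is the
#' kernel-weighted CTM regressor, `beta0(s)` is one draw per day of a
#' mean-zero Gaussian process with covariance `tau2 * exp(-d / rho)` over
#' all site locations *and* grid centroids (so the noise-free truth surface
#' is known for scoring predictions), and `eps ~ N(0, sigma2)` i.i.d.
#' Negative draws are clipped to 0; the clip count is recorded.
#'
#' @param ctm Gridded field tibble from [simulate_ctm_field()].
#' @param sites Scheduled site tibble from [assign_schedules()].
#' @param grid The grid the field lives on.
#' @param truth Named list with `beta0`, `beta1`, `tau2`, `rho`, `sigma2`.
#' @param kernel_decay Kernel decay (1/km) used to build `x~(s)`.
#' @param seed Integer seed.
#' @return List with `observations` (tibble `site_id, date, pm25`) and
#'   `truth` (the input parameters plus per-day local-intercept draws:
#'   `local_site` days x sites, `local_grid` days x cells, `dates`,
#'   `n_clipped`).
#' @export
simulate_observations <- function(ctm, sites, grid, truth, kernel_decay = 0.1,
                                  seed) {
  need <- c("beta0", "beta1", "tau2", "rho", "sigma2")
  if (!all(need %in% names(truth)))
    stop("truth must specify ", paste(need, collapse = ", "), call. = FALSE)
  stopifnot(truth$tau2 >= 0, truth$sigma2 >= 0, truth$rho > 0)
  if (!all(in_grid(grid, sites$x, sites$y)))
    stop("all sites must lie inside the grid extent", call. = FALSE)
  dates <- sort(unique(ctm$date))
  cent <- grid_centroids(grid)
  pts <- rbind(cbind(sites$x, sites$y), cbind(cent$x, cent$y))
  ns <- nrow(sites); nc <- nrow(cent); nd <- length(dates)

  L <- NULL
  if (truth$tau2 > 0)
    L <- chol(truth$tau2 * exp_corr(pair_dist(pts), truth$rho) +
              diag(1e-10 * max(truth$tau2, 1), nrow(pts)))

  # per-day regressor at each site
  xt <- matrix(NA_real_, nd, ns)
  for (d in seq_len(nd)) {
    v <- field_day_values(ctm, grid, dates[d])
    for (i in seq_len(ns))
      xt[d, i] <- build_weighted_regressor(sites$x[i], sites$y[i], v, grid,
                                           kernel_decay)
  }

  res <- with_seed(seed, {
    b <- if (is.null(L)) matrix(0, nd, ns + nc) else
      matrix(stats::rnorm(nd * (ns + nc)), nd) %*% L
    eps <- if (truth$sigma2 > 0)
      matrix(stats::rnorm(nd * ns, sd = sqrt(truth$sigma2)), nd, ns)
    else matrix(0, nd, ns)
    list(b = b, eps = eps)
  })

  y <- truth$beta0 + res$b[, seq_len(ns), drop = FALSE] +
    truth$beta1 * xt + res$eps
  keep <- matrix(FALSE, nd, ns)
  for (i in seq_len(ns)) {
    sd_i <- scheduled_dates(sites$schedule[i], sites$offset[i], dates)
    keep[match(sd_i, dates), i] <- TRUE
  }
  n_clipped <- sum(y < 0 & keep)
  y[y < 0] <- 0
  obs <- tibble::tibble(
    site_id = rep(sites$site_id, each = nd),
    date = rep(dates, ns),
    pm25 = as.numeric(y)
  )[as.logical(keep), ]
  obs <- dplyr::arrange(obs, .data$site_id, .data$date)

  list(
    observations = obs,
    truth = c(truth, list(
      kernel_decay = kernel_decay, dates = dates,
      local_site = res$b[, seq_len(ns), drop = FALSE],
      local_grid = res$b[, ns + seq_len(nc), drop = FALSE],
      site_regressor = xt,
      n_clipped = n_clipped
    ))
  )
}

#' Apply a multiplicative bias to one network's observations
#'
#' Scales all records belonging to the named network by a constant factor,
#' e.g. `multiplier = 0.85` to emulate a remote network reading 15% low
#' relative to the regulatory network.
#'
#' @param obs Observation tibble (`site_id, date, pm25`).
#' @param sites Site tibble carrying the `network` labels.
#' @param network `"urban"` or `"remote"`.
#' @param multiplier Positive scale factor.
#' @return The observation tibble with the named network rescaled.
#' @export
apply_network_bias <- function(obs, sites, network, multiplier) {
  if (!is.finite(multiplier) || multiplier <= 0)
    stop("multiplier must be > 0", call. = FALSE)
  if (!network %in% c("urban", "remote"))
    stop("unknown network label: ", network, call. = FALSE)
  ids <- sites$site_id[sites$network == network]
  dplyr::mutate(obs, pm25 = ifelse(.data$site_id %in% ids,
                                   .data$pm25 * multiplier, .data$pm25))
}
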