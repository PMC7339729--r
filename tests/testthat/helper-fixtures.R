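# Shared fixtures and independent oracle helpers, all built in code.

# Monte Carlo standard error of a chain mean by batch means.
mcse <- function(x, n_batch = 20) {
  m <- floor(length(x) / n_batch)
  bm <- vapply(seq_len(n_batch), function(b)
    mean(x[((b - 1) * m + 1):(b * m)]), numeric(1))
  stats::sd(bm) / sqrt(n_batch)
}

# A small fully-observed world: grid, daily CTM field, sites with daily
# schedules, and noise-controlled observations.
tiny_world <- function(n_sites = 6, nx = 8, ny = 8, cell = 10, n_days = 1,
                       truth = list(beta0 = 1, beta1 = 1, tau2 = 0.5,
                                    rho = 30, sigma2 = 0.3),
                       kernel_decay = 0.1, seed = 42) {
  grid <- make_grid(nx, ny, cell)
  dates <- as.Date("2014-01-01") + seq_len(n_days) - 1
  ctm <- simulate_ctm_field(grid, dates, base_level = 10, day_sd = 1,
                            range_km = 40, seed = seed)
  e <- dsfusion:::grid_extent(grid)
  sites <- with_test_seed(seed + 1, tibble::tibble(
    site_id = sprintf("S%02d", seq_len(n_sites)),
    x = runif(n_sites, e$xmin + 1, e$xmax - 1),
    y = runif(n_sites, e$ymin + 1, e$ymax - 1),
    network = "urban", schedule = "daily", offset = 0L))
  sim <- simulate_observations(ctm, sites, grid, truth,
                               kernel_decay = kernel_decay, seed = seed + 2)
  list(grid = grid, dates = dates, ctm = ctm, sites = sites,
       obs = sim$observations, truth = sim$truth,
       truth_pars = truth, kernel_decay = kernel_decay)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Independent brute-force kernel regressor: explicit loop over every cell
# of the grid, no shared code with the package's windowed implementation
# beyond the definition itself.
oracle_regressor <- function(x, y, ctm_values, grid, kernel_decay) {
  num <- 0; den <- 0
  cc_x <- round((x - grid$origin[1]) / grid$cell_size)
  cc_y <- round((y - grid$origin[2]) / grid$cell_size)
  for (cx in 0:(grid$nx - 1)) for (cy in 0:(grid$ny - 1)) {
    if (abs(cx - cc_x) > 3 || abs(cy - cc_y) > 3) next
    gx <- grid$origin[1] + cx * grid$cell_size
    gy <- grid$origin[2] + cy * grid$cell_size
    w <- exp(-kernel_decay * sqrt((gx - x)^2 + (gy - y)^2))
    num <- num + w * ctm_values[cy * grid$nx + cx + 1]
    den <- den + w
  }
  num / den
}
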