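# Internal helpers shared across modules.

# Pairwise Euclidean distances between two coordinate matrices (n x 2, m x 2).
pair_dist <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

# Exponential correlation exp(-d / rho)
exp_corr <- function(d, rho) exp(-d / rho)

# Deterministic per-day seed derived from a master seed and a day index,
# kept in [1, 2^31 - 2] so it is a valid R integer seed. Splitmix-style
# integer mix so nearby (seed, day) pairs decorrelate.
day_seed <- function(master_seed, day_index) {
  stopifnot(length(master_seed) == 1)
  v <- (as.double(master_seed) %% 2147483647) * 48271 +
    (as.double(day_index) + 1) * 69621
  v <- (v * 16807) %% 2147483647
  as.integer(v %% 2147483646) + 1L
}

# 0-based index of each date within the simulation period
day_index <- function(dates, origin_date) {
  as.integer(as.Date(dates) - as.Date(origin_date))
}

# Convert a long (date, cell) field tibble for one day into the vector of
# values ordered like grid_centroids(grid).
field_day_values <- function(field, grid, date) {
  d <- field[field$date == as.Date(date), , drop = FALSE]
  if (nrow(d) == 0) stop("no field values for date ", date, call. = FALSE)
  if (nrow(d) != n_cells(grid))
    stop("field/grid mismatch on ", date, call. = FALSE)
  ord <- order(d$cell_y, d$cell_x)
  d$pm25[ord]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state,
# so that every simulation operation is a pure function of (inputs, seed).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
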