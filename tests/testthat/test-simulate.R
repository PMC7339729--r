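test_that("no variation gives a constant field; fixed seed reproduces", {
  g <- make_grid(5, 5, 12)
  dates <- as.Date("2014-03-01") + 0:3
  f <- simulate_ctm_field(g, dates, base_level = 6, hotspots = NULL,
                          day_sd = 0, seed = 1)
  expect_true(all(f$pm25 == 6))
  f1 <- simulate_ctm_field(g, dates, seed = 9)
  f2 <- simulate_ctm_field(g, dates, seed = 9)
  expect_identical(f1, f2)
  expect_false(identical(
    f1$pm25, simulate_ctm_field(g, dates, seed = 10)$pm25))
  expect_error(simulate_ctm_field(g, as.Date(character(0)), seed = 1),
               "non-empty")
})

test_that("daily anomalies have approximately exponential correlation", {
  g <- make_grid(8, 8, 10)
  dates <- as.Date("2014-01-01") + 0:199
  range_km <- 30
  f <- simulate_ctm_field(g, dates, base_level = 50, hotspots = NULL,
                          day_sd = 1, range_km = range_km, seed = 21)
  m <- matrix(f$pm25, nrow = length(dates), byrow = TRUE)  # days x cells
  anom <- sweep(m, 2, colMeans(m))
  cent <- grid_centroids(g)
  d <- dsfusion:::pair_dist(cbind(cent$x, cent$y))
  cc <- stats::cor(anom)
  # bin pairs by distance and compare mean correlation to exp(-d/range)
  for (bin in list(c(5, 15), c(15, 25), c(25, 40))) {
    sel <- d > bin[1] & d <= bin[2] & upper.tri(d)
    expect_equal(mean(cc[sel]), mean(exp(-d[sel] / range_km)),
                 tolerance = 0.12)
  }
})

test_that("monitor placement respects networks, domain and determinism", {
  g <- make_grid(10, 10, 12)
  s <- place_monitors(g, 0, 5, seed = 5)
  expect_equal(nrow(s), 5)
  expect_true(all(s$network == "remote"))
  expect_true(all(dsfusion:::in_grid(g, s$x, s$y)))
  expect_false(any(duplicated(s$site_id)))
  expect_identical(place_monitors(g, 7, 3, seed = 2),
                   place_monitors(g, 7, 3, seed = 2))
  expect_error(place_monitors(g, 100, 10, seed = 1), "more sites")
  expect_error(place_monitors(g, 0, 0, seed = 1), ">= 1")
})

test_that("urban sites sit closer to hotspots than remote sites", {
  g <- make_grid(12, 12, 12)
  hs <- default_hotspots(g)
  mean_hotspot_dist <- function(s) {
    d <- dsfusion:::pair_dist(cbind(s$x, s$y), cbind(hs$x, hs$y))
    mean(apply(d, 1, min))
  }
  diffs <- vapply(1:50, function(seed) {
    s <- place_monitors(g, 10, 10, hs, seed = seed)
    mean_hotspot_dist(s[s$network == "urban", ]) -
      mean_hotspot_dist(s[s$network == "remote", ])
  }, numeric(1))
  expect_lt(mean(diffs), 0)
})

test_that("schedule assignment reproduces the target frequency mix", {
  g <- make_grid(40, 40, 12)
  s <- place_monitors(g, 1000, 0, seed = 1)
  s <- assign_schedules(s, urban_fracs = c(0.13, 0.47, 0.40), seed = 2)
  fr <- table(s$schedule) / nrow(s)
  expect_lt(abs(fr[["one_in_six"]] - 0.13), 0.05)
  expect_lt(abs(fr[["one_in_three"]] - 0.47), 0.05)
  expect_lt(abs(fr[["daily"]] - 0.40), 0.05)

  all_daily <- assign_schedules(s, urban_fracs = c(0, 0, 1), seed = 3)
  expect_true(all(all_daily$schedule == "daily"))
  expect_error(assign_schedules(s, urban_fracs = c(-0.1, 0.6, 0.5), seed = 1),
               "nonnegative")
})

test_that("all remote sites share one 1-in-3 schedule", {
  g <- make_grid(10, 10, 12)
  s <- assign_schedules(place_monitors(g, 5, 8, seed = 4), seed = 5)
  rem <- s[s$network == "remote", ]
  expect_true(all(rem$schedule == "one_in_three"))
  expect_equal(length(unique(rem$offset)), 1)
  dates <- as.Date("2014-01-01") + 0:29
  sets <- lapply(seq_len(nrow(rem)), function(i)
    dsfusion:::scheduled_dates(rem$schedule[i], rem$offset[i], dates))
  for (i in seq_along(sets)[-1]) expect_identical(sets[[i]], sets[[1]])
})

test_that("schedules select exactly the matching day-index residues", {
  dates <- as.Date("2014-01-01") + 0:29
  d3 <- dsfusion:::scheduled_dates("one_in_three", 1L, dates)
  expect_identical(d3, dates[(0:29) %% 3 == 1])
  d6 <- dsfusion:::scheduled_dates("one_in_six", 4L, dates)
  expect_identical(d6, dates[(0:29) %% 6 == 4])
  expect_identical(dsfusion:::scheduled_dates("daily", 0L, dates), dates)
})

test_that("noise-free observations equal the weighted regressor exactly", {
  w <- tiny_world(n_sites = 5, n_days = 3,
                  truth = list(beta0 = 0, beta1 = 1, tau2 = 0, rho = 30,
                               sigma2 = 0))
  for (k in seq_len(nrow(w$obs))) {
    r <- w$obs[k, ]
    s <- w$sites[w$sites$site_id == r$site_id, ]
    v <- dsfusion:::field_day_values(w$ctm, w$grid, r$date)
    expect_equal(r$pm25, oracle_regressor(s$x, s$y, v, w$grid,
                                          w$kernel_decay),
                 tolerance = 1e-10)
  }
})

test_that("constant generative model yields constant observations", {
  w <- tiny_world(n_sites = 4, n_days = 2,
                  truth = list(beta0 = 2, beta1 = 0, tau2 = 0, rho = 30,
                               sigma2 = 0))
  expect_true(all(w$obs$pm25 == 2))
})

test_that("local intercept draws match the exponential variogram", {
  g <- make_grid(12, 12, 10)
  dates <- as.Date("2014-01-01") + 0:199
  ctm <- simulate_ctm_field(g, dates, base_level = 30, hotspots = NULL,
                            day_sd = 0, seed = 1)
  e <- dsfusion:::grid_extent(g)
  sites <- with_test_seed(8, tibble::tibble(
    site_id = sprintf("S%03d", 1:100),
    x = runif(100, e$xmin, e$xmax), y = runif(100, e$ymin, e$ymax),
    network = "urban", schedule = "daily", offset = 0L))
  tau2 <- 1; rho <- 40
  sim <- simulate_observations(ctm, sites, g,
    list(beta0 = 0, beta1 = 0, tau2 = tau2, rho = rho, sigma2 = 0),
    seed = 99)
  b <- sim$truth$local_site                 # 200 days x 100 sites
  d <- dsfusion:::pair_dist(cbind(sites$x, sites$y))
  # semivariogram: E[(b_i - b_j)^2] / 2 = tau2 * (1 - exp(-d/rho))
  for (bin in list(c(5, 15), c(15, 25), c(25, 39))) {
    sel <- which(d > bin[1] & d <= bin[2] & upper.tri(d), arr.ind = TRUE)
    gam <- mean(vapply(seq_len(nrow(sel)), function(k)
      mean((b[, sel[k, 1]] - b[, sel[k, 2]])^2) / 2, numeric(1)))
    model <- mean(tau2 * (1 - exp(-d[sel] / rho)))
    expect_lt(abs(gam - model) / model, 0.10)
  }
})

test_that("network bias rescales exactly and composes multiplicatively", {
  w <- tiny_world(n_sites = 6, n_days = 4)
  sites <- w$sites
  sites$network[4:6] <- "remote"
  rem_ids <- sites$site_id[4:6]
  m0 <- mean(w$obs$pm25[w$obs$site_id %in% rem_ids])
  u0 <- w$obs$pm25[!w$obs$site_id %in% rem_ids]

  b1 <- apply_network_bias(w$obs, sites, "remote", 0.85)
  expect_equal(mean(b1$pm25[b1$site_id %in% rem_ids]), 0.85 * m0)
  expect_equal(b1$pm25[!b1$site_id %in% rem_ids], u0)

  expect_identical(apply_network_bias(w$obs, sites, "remote", 1.0), w$obs)
  b2 <- apply_network_bias(b1, sites, "remote", 0.85)
  expect_equal(mean(b2$pm25[b2$site_id %in% rem_ids]), 0.7225 * m0)
  expect_error(apply_network_bias(w$obs, sites, "rural", 0.9), "unknown")
})

test_that("simulation is deterministic and respects schedules", {
  g <- make_grid(8, 8, 12)
  dates <- as.Date("2014-01-01") + 0:11
  ctm <- simulate_ctm_field(g, dates, seed = 1)
  sites <- assign_schedules(place_monitors(g, 6, 3, seed = 2), seed = 3)
  tr <- list(beta0 = 1, beta1 = 1, tau2 = 0.5, rho = 30, sigma2 = 0.2)
  s1 <- simulate_observations(ctm, sites, g, tr, seed = 4)
  s2 <- simulate_observations(ctm, sites, g, tr, seed = 4)
  expect_identical(s1$observations, s2$observations)
  # at most one record per site-day, dates consistent with schedule
  expect_false(any(duplicated(s1$observations[c("site_id", "date")])))
  for (i in seq_len(nrow(sites))) {
    oi <- s1$observations[s1$observations$site_id == sites$site_id[i], ]
    expect_identical(oi$date,
      dsfusion:::scheduled_dates(sites$schedule[i], sites$offset[i], dates))
  }
})
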