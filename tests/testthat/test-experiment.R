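# Small paired-scenario world reused across tests in this file.
pair_world <- function(n_days = 12, n_urban = 8, n_remote = 3, seed = 1) {
  grid <- make_grid(8, 8, 12)
  dates <- as.Date("2014-01-01") + seq_len(n_days) - 1
  ctm <- simulate_ctm_field(grid, dates, seed = seed)
  sites <- assign_schedules(place_monitors(grid, n_urban, n_remote,
                                           seed = seed + 1),
                            urban_fracs = c(0, 0, 1), seed = seed + 2)
  sim <- simulate_observations(ctm, sites, grid,
    list(beta0 = 1, beta1 = 1, tau2 = 0.5, rho = 40, sigma2 = 0.3),
    seed = seed + 3)
  list(grid = grid, dates = dates, ctm = ctm, sites = sites,
       obs = sim$observations)
}

test_that("without remote sites the two scenarios are identical", {
  w <- pair_world(n_days = 4, n_remote = 0)
  cfg <- ds_config(n_iter = 300, n_burn = 100, seed = 5)
  sc <- run_scenario_pair(w$sites, w$obs, w$ctm, w$grid, cfg)
  expect_identical(sc$baseline, sc$augmented)
  expect_true(all(sc$days$identical))
})

test_that("exactly 2/3 of days are unaffected by a 1-in-3 remote network", {
  w <- pair_world(n_days = 12)
  cfg <- ds_config(n_iter = 300, n_burn = 100, seed = 5)
  sc <- run_scenario_pair(w$sites, w$obs, w$ctm, w$grid, cfg)
  expect_equal(sum(sc$days$identical), 8)
  # identity is bitwise on those days
  for (d in w$dates[sc$days$identical]) {
    expect_identical(sc$baseline[sc$baseline$date == d, ],
                     sc$augmented[sc$augmented$date == d, ])
  }
  # on remote-sample days the augmented fit used the scheduled extra records
  rem <- w$sites[w$sites$network == "remote", ]
  expected_extra <- vapply(w$dates, function(d)
    3 * (dsfusion:::day_index(d, w$dates[1]) %% 3 == rem$offset[1]),
    numeric(1))
  expect_equal(sc$days$n_remote, expected_extra)
  expect_false(any(sc$days$identical[expected_extra > 0]))
})

test_that("aggregation reduces constants to constants", {
  cent <- grid_centroids(make_grid(3, 3, 10))
  dates <- as.Date("2014-01-01") + 0:9
  surf <- dplyr::bind_rows(lapply(dates, function(d)
    dplyr::mutate(cent, date = d, pm25_mean = 4.2, pm25_se = 0.3)))
  a <- aggregate_surfaces(surf)
  expect_true(all(a$annual_mean == 4.2))
  expect_true(all(a$p98 == 4.2))
  expect_true(all(a$q1 == 4.2))
  expect_true(all(a$se_mean == 0.3))
})

test_that("98th percentile matches a sort-based oracle", {
  cent <- grid_centroids(make_grid(2, 2, 10))
  dates <- as.Date("2014-01-01") + 0:99
  with_test_seed(6, vals <- matrix(rgamma(400, 4, 0.5), nrow = 100))
  surf <- dplyr::bind_rows(lapply(seq_along(dates), function(i)
    dplyr::mutate(cent, date = dates[i], pm25_mean = vals[i, ],
                  pm25_se = 0)))
  a <- aggregate_surfaces(surf)
  an <- aggregate_surfaces(surf, pctl_method = "nearest_rank")
  for (cell in 1:4) {
    v <- sort(vals[, cell])
    # linear interpolation between order statistics at h = (n-1)p + 1
    h <- (100 - 1) * 0.98 + 1
    oracle <- v[floor(h)] + (h - floor(h)) * (v[floor(h) + 1] - v[floor(h)])
    expect_equal(a$p98[cell], oracle, tolerance = 1e-12)
    expect_equal(an$p98[cell], v[ceiling(0.98 * 100)])
    expect_gte(a$p98[cell], a$annual_mean[cell])
  }
})

test_that("sample-dates mode keeps exactly the scheduled days", {
  w <- pair_world(n_days = 12)
  sd <- sample_dates(w$sites, w$dates)
  expect_equal(length(sd), 4)
  rem_off <- w$sites$offset[w$sites$network == "remote"][1]
  expect_identical(sd, w$dates[(0:11) %% 3 == rem_off])
  cent <- grid_centroids(w$grid)
  surf <- dplyr::bind_rows(lapply(seq_along(w$dates), function(i)
    dplyr::mutate(cent, date = w$dates[i], pm25_mean = i, pm25_se = 0)))
  a <- aggregate_surfaces(surf, mode = "sample_dates", dates = sd)
  expect_true(all(a$annual_mean == mean(which(w$dates %in% sd))))
  expect_error(aggregate_surfaces(surf, mode = "sample_dates"), "dates")
})

test_that("quarterly means reconstruct the annual mean and shift linearly", {
  cent <- grid_centroids(make_grid(2, 2, 10))
  dates <- seq(as.Date("2014-01-01"), as.Date("2014-12-31"), by = "day")
  with_test_seed(2, vals <- rnorm(length(dates), 10, 2))
  surf <- dplyr::bind_rows(lapply(seq_along(dates), function(i)
    dplyr::mutate(cent, date = dates[i], pm25_mean = vals[i], pm25_se = 0)))
  a <- aggregate_surfaces(surf)
  qdays <- table((as.integer(format(dates, "%m")) - 1) %/% 3 + 1)
  recon <- (a$q1 * qdays[1] + a$q2 * qdays[2] + a$q3 * qdays[3] +
              a$q4 * qdays[4]) / sum(qdays)
  expect_equal(unname(recon), a$annual_mean, tolerance = 1e-12)
  # aggregation of (field + c) = aggregate(field) + c for mean statistics
  surf_c <- dplyr::mutate(surf, pm25_mean = pm25_mean + 1.5)
  ac <- aggregate_surfaces(surf_c)
  expect_equal(ac$annual_mean, a$annual_mean + 1.5)
  expect_equal(ac$q3, a$q3 + 1.5)
  expect_equal(ac$p98, a$p98 + 1.5)
})

test_that("difference surfaces subtract cellwise and antisymmetrically", {
  cent <- grid_centroids(make_grid(2, 2, 10))
  mk <- function(m, se) {
    a <- dplyr::mutate(cent, annual_mean = m, p98 = m + 1, q1 = m, q2 = m,
                       q3 = m, q4 = m, se_mean = se)
    attr(a, "mode") <- "entire_period"
    a
  }
  a <- mk(c(1, 2, 3, 4), c(0.1, 0.2, 0.3, 0.4))
  b <- mk(c(4, 3, 2, 1), c(0.4, 0.3, 0.2, 0.1))
  expect_true(all(difference_surface(a, a)$annual_mean == 0))
  dab <- difference_surface(a, b); dba <- difference_surface(b, a)
  expect_equal(dab$annual_mean, -dba$annual_mean)
  expect_equal(dab$annual_mean, c(-3, -1, 1, 3))
  expect_equal(dab$se_mean, c(-0.3, -0.1, 0.1, 0.3))
  bad <- mk(1:4, 1:4); attr(bad, "mode") <- "sample_dates"
  expect_error(difference_surface(a, bad), "modes")
})

test_that("case-study extraction crops consistently and aligns series", {
  w <- pair_world(n_days = 6)
  cfg <- ds_config(n_iter = 200, n_burn = 50, seed = 9)
  sc <- run_scenario_pair(w$sites, w$obs, w$ctm, w$grid, cfg)
  full <- list(xmin = -6, xmax = 90, ymin = -6, ymax = 90)
  focus <- w$sites$site_id[c(1, nrow(w$sites))]
  cs <- extract_case_study(sc, w$obs, w$sites, w$grid, full, focus)
  expect_identical(cs$baseline, sc$baseline)

  win <- list(xmin = 20, xmax = 70, ymin = 10, ymax = 80)
  inside <- w$sites[w$sites$x >= 20 & w$sites$x <= 70 &
                      w$sites$y >= 10 & w$sites$y <= 80, ]
  cs2 <- extract_case_study(sc, w$obs, w$sites, w$grid, win,
                            inside$site_id[1])
  # cropped cells are exactly the corresponding cells of the full surface
  expect_identical(
    cs2$baseline,
    sc$baseline[sc$baseline$x >= 20 & sc$baseline$x <= 70 &
                  sc$baseline$y >= 10 & sc$baseline$y <= 80, ])
  ser <- cs2$series
  n_rep <- sum(w$obs$site_id == inside$site_id[1])
  expect_equal(nrow(ser), n_rep)
  expect_true(all(c("observed", "baseline", "augmented") %in% names(ser)))
  expect_error(extract_case_study(sc, w$obs, w$sites, w$grid, win, "nope"),
               "unknown")
})
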